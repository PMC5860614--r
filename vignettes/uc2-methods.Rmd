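---
title: "Neutralized single-query compound search: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutralized single-query compound search: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uc2)
```

## The annotation problem

An accurate-mass peak from an untargeted metabolomics run is annotated by
looking up candidate compounds whose mass is compatible with the detected
*m/z* under some ionization hypothesis. Compound collections complicate
this in four ways: entries may be registered as permanently charged
molecules; entries may contain several components (salts, hydrates);
stereoisomer variants multiply records without being distinguishable by
mass; and the same compound recurs across collections. A detected ion
gives no direct clue whether it is an adduct of a neutral molecule
([M+H]⁺, [M−H]⁻) or a molecular ion of an intrinsically charged one
([M]⁺, [M]⁻), so the conventional workaround queries both the
adduct-implied neutral mass and the raw *m/z* against as-registered
masses — and the union of the two routes is where false positives enter.

## The model

Every record is reduced to a *normalized entry*:

* **Representative component.** A record's canonical SMILES is split at
  dot-disconnections; the component with the largest average molecular
  weight represents the record (`is_fragmented` records the multiplicity).
  Ties are broken by the lexicographically smallest canonical SMILES, so
  selection is deterministic.
* **Tentative neutralization.** For net charge $q$, the representative's
  formula loses $q$ hydrogens ($q>0$) or gains $|q|$ ($q<0$). Writing $P$
  for the registered ionic monoisotopic mass (electron-corrected) and
  $m_p$ for the proton mass, the neutralized mass is exactly
  $M = P - q\,m_p$. The adjustment is pure bookkeeping — the resulting
  formula need not be a stable molecule — but it places charged and
  uncharged registrations on one mass scale: a +1 cation's [M]⁺ ion sits
  at precisely the [M+H]⁺ *m/z* of its neutralized mass.
* **Connectivity key.** The first 14-letter block of the standard
  InChIKey, computed on the representative *as registered* (standard InChI
  normalization absorbs protonation differences), keys the entry. The
  block encodes connectivity only, so stereoisomers, isotopologues and
  acid/conjugate-base pairs share it; entries sharing a key collapse into
  one group across source databases. Zwitterions with net charge zero get
  no hydrogen adjustment.

A search converts the observed *m/z* to a neutral-mass hypothesis per
assumed adduct, $M = (mz \cdot z - \delta)/n$, and scans the neutralized
masses once. Each hit is annotated by comparing its members' registered
charges with the adduct polarity: `charged-entry-positive-mode` /
`charged-entry-negative-mode` mark molecular-ion interpretations in
matching polarity, `positive-entry-negative-mode` marks the pigment-cation
case (a +1 entry at ionic mass − 2 protons in negative mode, as flavylium
anthocyanins are genuinely detected), and `negative-entry-positive-mode`
its mirror. Flags inform; they never drop a hit.

The *conventional baseline* reproduces the dual strategy: route (a)
matches as-registered masses against the default-adduct-implied neutral
mass, route (b) against the raw *m/z*; candidates are counted per record
with no connectivity deduplication.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| mass tolerance | 5 ppm | typical high-resolution instrument accuracy; `mass_tolerance()` also accepts mDa |
| default adducts | [M+H]⁺ / [M−H]⁻ | the standard single-charge assumption per polarity; registry includes Na/K/NH₄/Cl adducts, [M]±, dimers, 2± species |
| proton mass | 1.00727645 Da | H-atom monoisotopic mass minus electron mass, so neutralization and adduct arithmetic cancel exactly in double precision |
| electron mass | 0.00054858 Da | folded into each adduct's mass offset |
| window bounds | inclusive | boundary masses are legitimate matches |

Monoisotopic masses are indexed for search (the quantity high-resolution
MS measures); average masses are stored alongside, and representative
selection uses average molecular weight. Element masses come from a fixed
internal table (most-abundant-isotope masses and standard atomic
weights), needed because neutralized formulas have no structure object to
hand to a toolkit.

## Numerical and degenerate-input choices

* Mass identities are kept exact in double precision: stored masses are
  full-precision doubles and the [M]⁺/[M+H]⁺ identity for +1 entries holds
  to well below 1e−9 Da. The store's TSV exchange format writes masses as
  fixed 6-decimal text; a loaded store answers every membership and
  lookup query identically, and a second export is byte-identical.
* A representative whose positive charge exceeds its hydrogen count (a
  bare metal cation) cannot be neutralized: it is flagged
  `non_neutralizable`, excluded from every index, and retained in the
  provenance output. Unparsable records are skipped with a warning and a
  count, never fatally mid-build; records failing InChI generation are
  flagged `inchi_failure`.
* Two entries sharing a skeleton but disagreeing on neutralized formula
  (possible for exotic charge states) split into (skeleton, formula)
  groups with a warning rather than silently merging.
* `upsert_entry()` returns the updated store — R's copy-on-modify
  semantics make an in-place group handle meaningless — and is idempotent
  for a repeated (database, record id).

## The synthetic benchmark

`generate_collection()` plants a curated set of 47 real small molecules
across two pseudo-databases: neutral metabolites, a zwitterion,
stereoisomer families (hexoses, tartrates), quaternary-ammonium and
pyridinium cations, sulfonate/sulfate anions, salts and a hydrate,
cross-database duplicates, a bare metal cation, corrupt rows, and decoys.
Each decoy is built by inverting a baseline matching condition: a
decoy cation's trigger peak sits at its ionic mass *plus* one proton, so
the conventional neutral-mass route hits it while the neutralized index
(offset by a second proton) cannot; raw-*m/z* decoys sit exactly on a
neutral compound's registered mass where no adduct hypothesis lands.
Every expected skeleton, formula and mass in the manifest was frozen from
an independent structure toolkit when the template set was curated, so
`verify_manifest()` compares the implementation against genuinely
external values. `generate_peaks()` emits each target's theoretical ion
peaks (both polarities for neutrals, molecular ions for charged species,
and the [M−2H]⁻ pigment-style peak for every +1 entry), the decoy
triggers, and empty-region peaks, with per-peak expected outcomes derived
by brute force from the manifest masses alone. Defaults: exact peaks
(0 ppm jitter), ~60 peaks, 5 decoys; generation is byte-identical per
seed, and package code never touches the session RNG state.

What the benchmark emulates — and what it does not: it reproduces the
*mechanisms* (charged entries, salts, stereo families, redundancy, the
two baseline routes and their failure modes) at desk scale with exact
peaks. It does not emulate live-database scale or composition, instrument
noise, isotope patterns, in-source fragments, or the non-uniform mass
distribution of real metabolomes, so benchmark percentages (e.g. the
share of conventional-only false positives) characterize the construction,
not any particular biological dataset.

## Design choices where the design was open

* **Both mass kinds stored.** "Formula weight" is ambiguous; storing
  monoisotopic and average and indexing monoisotopic serves the MS use
  case without discarding information.
* **Skeleton from the registered form.** Neutralization is applied to the
  formula only; the InChIKey is computed on the representative as
  registered, relying on standard InChI's protonation normalization. This
  also means labeled and unlabeled isotopologues merge — documented
  behavior of the first block.
* **Hydrogen adjustment on the representative only**, after selection,
  even when several components are charged — consistent with
  representative-based indexing.
* **Exclusive-result percentages** use peaks-with-any-result as
  denominator, matching how such comparisons tally exclusive hits.
* **Baseline scope.** The conventional baseline queries the same
  normalized artifact's member masses, so non-neutralizable bare ions are
  absent from both searches; a live-database baseline would include them.

## Known limitations

Structure curation is out of scope: erroneous source structures (wrong
valences, repeat units) survive normalization and can still cause
exclusive hits, as they do in real collections. The store is an in-memory
index serialized to TSV, sized for compound collections up to the
hundreds of thousands of records, not a server database. MS/MS evidence,
isotope-pattern and retention-time scoring are deliberately outside the
method: this is a front-end that makes the *candidate list* smaller and
honest, not a full annotation engine.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full curated collection
(47 records, ~60 peaks), 100 randomized 20–25-entry stores for the
brute-force lookup equivalence, and 200 random masses across the full
adduct registry for round-trip arithmetic — sizes chosen so the whole
suite re-runs in seconds while every code path is exercised.
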