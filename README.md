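# uc2

Single-query accurate-mass compound search over charge-neutralized,
connectivity-deduplicated compound collections, for metabolite annotation
in MS-based metabolomics.

## The problem

Public compound databases register the "same" metabolite in many forms:
permanently charged molecules (quaternary ammonium ions, flavylium
pigments, sulfonates), multi-component entries (salts, hydrates),
stereoisomer families, and duplicates across collections. Annotating an
accurate-mass peak against such records conventionally requires *two*
lookups — the neutral mass implied by an assumed adduct (e.g.
[M+H]<sup>+</sup>), and the raw detected *m/z* for intrinsically charged
species — and the union of both routes admits false positives: a cation
whose registered ionic mass happens to equal the neutral mass implied by
some peak is returned as an "[M+H]<sup>+</sup> match" even though a cation
cannot form that adduct.

## The method

Each record is standardized before indexing:

1. **Component split** — multi-component records (salts, hydrates) are
   split; the component with the largest molecular weight is kept as
   representative.
2. **Tentative neutralization** — a representative with net charge *q*
   has *q* hydrogens removed from (or, for anions, |*q*| added to) its
   formula: for a cation, M<sub>neutral</sub> = M<sub>ion</sub> −
   *q*·m<sub>proton</sub>. Not chemistry, but exact mass bookkeeping.
3. **Connectivity key** — the first block (14 letters) of the standard
   InChIKey of the representative, which erases stereochemistry, isotopes
   and protonation state, keys the entry; records sharing it collapse into
   one group across databases.

A query then converts the observed *m/z* to a neutral mass under each
assumed adduct and searches the neutralized masses **once**. A +1 cation's
molecular ion [M]<sup>+</sup> sits at exactly the [M+H]<sup>+</sup> m/z of
its neutralized mass, so charged and uncharged compounds are retrieved by
the same query, and each hit is annotated when its registered charge is
inconsistent with the assumed adduct (e.g. a cation matched in negative
mode, plausibly a [M−2H]<sup>−</sup> ion). The conventional dual search is
implemented as a baseline, plus an evaluation harness and a deterministic
synthetic-collection generator with ground-truth manifests.

## Worked example

```r
library(uc2)

recs <- normalize_records(data.frame(
  db_name   = "demo",
  record_id = c("r1", "r2", "r3"),
  name      = c("alpha-D-glucose", "alpha-D-galactose", "sodium acetate"),
  structure = c("OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@@H]1O",
                "OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@H]1O",
                "CC(=O)[O-].[Na+]")))
store <- build_store(recs)
store
#> uc2_store: 2 groups, 3 members, 0 rejected entries

uc2_search(store, 181.070664, "[M+H]+")[, c("skeleton", "neutral_formula",
                                            "neutral_monoisotopic_mass",
                                            "error_ppm")]
#>         skeleton neutral_formula neutral_monoisotopic_mass    error_ppm
#> 1 WQZGKKKJIJFFOK         C6H12O6                  180.0634 -0.003088306
```

The two hexose stereoisomers arrive as a *single* group
(`WQZGKKKJIJFFOK`), and the sodium acetate record was reduced to its
acetate component and neutralized to acetic acid (`C2H4O2`, 60.021129 Da)
— query `59.013853` in negative mode and it is found as [M−H]<sup>−</sup>
with its −1 charge signature attached.

A thin command-line wrapper ships at `inst/cli/uc2.R`
(`build` / `search` / `eval` / `fixtures` subcommands).

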