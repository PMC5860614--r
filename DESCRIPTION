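Package: uc2
Title: Accurate-Mass Compound Search over Charge-Neutralized,
    Connectivity-Deduplicated Compound Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds searchable indexes of compound-database records for
    metabolite annotation in mass-spectrometry-based metabolomics.
    Records are standardized by splitting multi-component entries
    (salts, hydrates), keeping the largest component as representative,
    tentatively neutralizing charged species at the formula level by
    adding or removing hydrogens, and collapsing stereoisomers and
    cross-database duplicates on the first (connectivity) block of the
    standard InChIKey.  Accurate-mass queries against the neutralized
    masses retrieve charged and uncharged compounds in a single pass and
    annotate hits whose registered charge is inconsistent with the
    assumed adduct.  A conventional dual search (default adduct plus raw
    m/z against as-registered masses) is provided as a baseline, together
    with an evaluation harness and a deterministic synthetic-collection
    generator with ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
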