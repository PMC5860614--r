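# Shared fixture benchmark, built once per test run.  Seed 42 is the fixed
# benchmark condition; the corrupt planted rows make parse_structures warn,
# which is part of the design and silenced here.

.fx_env <- new.env(parent = emptyenv())

fixture_manifest <- function() {
  if (is.null(.fx_env$manifest)) {
    dir <- file.path(tempdir(), "uc2-fixture-benchmark")
    .fx_env$manifest <- generate_collection(dir, seed = 42L)
  }
  .fx_env$manifest
}

fixture_store <- function() {
  if (is.null(.fx_env$store)) {
    .fx_env$store <- suppressWarnings(build_fixture_store(fixture_manifest()))
  }
  .fx_env$store
}

fixture_peaks <- function() {
  if (is.null(.fx_env$peaks)) {
    .fx_env$peaks <- generate_peaks(fixture_manifest(), seed = 42L)
  }
  .fx_env$peaks
}

# Synthetic normalized-entry tables (no chemistry involved) for store-level
# property tests: random masses, random skeleton keys.
random_entries <- function(n, seed) {
  withr::with_seed(seed, {
    skel <- vapply(seq_len(n), function(i) {
      paste(sample(LETTERS, 14, replace = TRUE), collapse = "")
    }, "")
    mono <- round(stats::runif(n, 50, 800), 6)
    data.frame(
      db_name = sample(c("dbA", "dbB"), n, replace = TRUE),
      record_id = sprintf("r%04d", seq_len(n)),
      name = sprintf("synthetic %d", seq_len(n)),
      skeleton = skel,
      neutral_formula = sprintf("C%dH%dO%d", sample(1:30, n, TRUE),
                                sample(1:40, n, TRUE), sample(1:10, n, TRUE)),
      neutral_monoisotopic_mass = mono,
      neutral_average_mass = mono + stats::runif(n, 0, 0.5),
      original_charge = sample(c(-1L, 0L, 0L, 0L, 1L), n, replace = TRUE),
      original_ionic_monoisotopic_mass = mono +
        stats::runif(n, -1, 1),
      is_fragmented = sample(c(TRUE, FALSE), n, replace = TRUE),
      flag = "", stringsAsFactors = FALSE)
  })
}

write_smiles_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
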