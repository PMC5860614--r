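# Adduct arithmetic and the two search semantics.

test_that("adduct arithmetic matches the documented constants", {
  expect_equal(mz_from_neutral_mass(180.0634, "[M+H]+"), 181.0707,
               tolerance = 5e-5)
  expect_equal(mz_from_neutral_mass(60.0211, "[M-H]-"), 59.0138,
               tolerance = 5e-5)
  expect_equal(mz_from_neutral_mass(100, "[M]+"), 100 - 0.000549,
               tolerance = 1e-6)
  expect_equal(mz_from_neutral_mass(100, "[M]-"), 100 + 0.000549,
               tolerance = 1e-6)
  expect_equal(neutral_mass_from_mz(181.0707, "[M+H]+"), 180.0634,
               tolerance = 5e-5)
  expect_equal(neutral_mass_from_mz(74.0964, "[M+H]+"), 73.0891,
               tolerance = 5e-5)
  # doubly charged and dimeric species follow the (n, z, delta) model
  reg <- uc2_adducts()
  expect_equal(mz_from_neutral_mass(500, reg[["[M+2H]2+"]]),
               (500 + 2 * uc2_constants()[["proton_mass"]]) / 2)
  expect_equal(mz_from_neutral_mass(200, reg[["[2M+H]+"]]),
               2 * 200 + uc2_constants()[["proton_mass"]])
  expect_error(uc2_adducts("[M+Xx]+"), "unknown adduct")
  expect_error(neutral_mass_from_mz(0.5, "[M+H]+"), "non-positive")
})

test_that("mass-to-mz conversion inverts exactly over the whole registry", {
  reg <- uc2_adducts()
  M <- withr::with_seed(7, stats::runif(50, 50, 1500))
  for (a in reg) {
    back <- vapply(M, function(m) {
      neutral_mass_from_mz(mz_from_neutral_mass(m, a), a)
    }, numeric(1))
    expect_true(all(abs(back - M) < 1e-9), info = a$name)
  }
})

test_that("tolerance windows scale correctly in both units", {
  expect_equal(tolerance_window(100, mass_tolerance(10, "ppm")),
               c(lo = 99.999, hi = 100.001))
  expect_equal(tolerance_window(500, mass_tolerance(5, "mDa")),
               c(lo = 499.995, hi = 500.005))
  w1 <- tolerance_window(300, mass_tolerance(5, "ppm"))
  w2 <- tolerance_window(300, mass_tolerance(10, "ppm"))
  expect_equal(diff(w2), 2 * diff(w1), ignore_attr = TRUE)
  expect_error(mass_tolerance(-1), "value > 0")
})

test_that("stored cations are found at their molecular-ion m/z in one query", {
  store <- fixture_store()
  p <- uc2_constants()[["proton_mass"]]
  cats <- store$members[store$members$original_charge == 1L, ]
  for (i in seq_len(nrow(cats))) {
    ion <- cats$original_ionic_monoisotopic_mass[i]
    hits <- uc2_search(store, ion, "[M+H]+")
    expect_true(cats$group_id[i] %in% hits$group_id,
                info = paste("cation", cats$record_id[i]))
  }
  ans <- store$members[store$members$original_charge == -1L, ]
  for (i in seq_len(nrow(ans))) {
    ion <- ans$original_ionic_monoisotopic_mass[i]
    hits <- uc2_search(store, ion, "[M-H]-")
    expect_true(ans$group_id[i] %in% hits$group_id,
                info = paste("anion", ans$record_id[i]))
  }
})

test_that("stereoisomers arrive compiled as a single search hit", {
  store <- fixture_store()
  hits <- uc2_search(store, 181.070664, "[M+H]+")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$skeleton, "WQZGKKKJIJFFOK")
  expect_equal(nrow(uc2_search(store, 9999, "[M+H]+")), 0L)
  expect_error(uc2_search(store, 181.07, list()), "empty adduct")
  expect_error(uc2_search(store, 181.07, c("[M+H]+", "[M-H]-")),
               "one polarity")
})

test_that("charge-consistency flags annotate without removing hits", {
  store <- fixture_store()
  p <- uc2_constants()[["proton_mass"]]
  tma <- query_by_skeleton(store, "QEMXHQIAXOOASZ")
  ion <- tma$members$original_ionic_monoisotopic_mass[1]

  pos <- uc2_search(store, ion, "[M+H]+")
  row <- pos[pos$skeleton == "QEMXHQIAXOOASZ", ]
  expect_equal(row$charge_mismatch, "charged-entry-positive-mode")

  # the pigment-cation scenario: a +1 entry picked up in negative mode
  neg <- uc2_search(store, ion - 2 * p, "[M-H]-")
  row <- neg[neg$skeleton == "QEMXHQIAXOOASZ", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$charge_mismatch, "positive-entry-negative-mode")

  # uncharged hits carry no flag
  glc <- uc2_search(store, 181.070664, "[M+H]+")
  expect_equal(glc$charge_mismatch, "none")

  # anion matched in its own polarity: molecular-ion interpretation
  msa <- query_by_skeleton(store, "AFVFQIVMOAPDHO")
  neg2 <- uc2_search(store, msa$members$original_ionic_monoisotopic_mass[1],
                     "[M-H]-")
  expect_equal(neg2$charge_mismatch[neg2$skeleton == "AFVFQIVMOAPDHO"],
               "charged-entry-negative-mode")

  flagged <- flag_charge_mismatch(row, "[M-H]-", store)
  expect_equal(flagged$charge_mismatch, "positive-entry-negative-mode")
})

test_that("the conventional dual search admits the planted decoys", {
  store <- fixture_store()
  m <- fixture_manifest()
  for (i in seq_len(nrow(m$decoys))) {
    d <- m$decoys[i, ]
    adduct <- if (d$mode == "positive") "[M+H]+" else "[M-H]-"
    conv <- conventional_search(store, d$trigger_mz, adduct)
    hit <- conv[conv$record_id == d$record_id, ]
    expect_gt(nrow(hit), 0)
    expect_equal(unique(hit$baseline_route), d$route)
    # the single-query search does not fall for it
    u <- uc2_search(store, d$trigger_mz, adduct)
    expect_false(d$record_id %in% store$members$record_id[
      match(u$group_id, store$members$group_id)])
    expect_false(any(u$group_id %in% conv$group_id[
      conv$record_id == d$record_id]))
  }
})

test_that("both searches agree on uncharged single-component entries", {
  store <- fixture_store()
  mz <- mz_from_neutral_mass(194.080376, "[M+H]+")  # caffeine
  u <- uc2_search(store, mz, "[M+H]+")
  conv <- conventional_search(store, mz, "[M+H]+")
  expect_setequal(unique(conv$group_id[conv$baseline_route ==
                                         "neutral-mass"]), u$group_id)
  # baseline counts records, not groups: both planted copies show up
  expect_equal(length(unique(paste(conv$db_name, conv$record_id))), 2L)
  expect_equal(nrow(u), 1L)
})
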