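# Record normalization: readers, component handling, neutralization
# pipeline.  Frozen skeletons and masses come from an independent InChI /
# periodic-table oracle.

sdf_text <- function(smiles) {
  # build V2000 molblocks at test time; no stored binary fixtures
  ChemmineOB::convertFormat("SMI", "SDF", paste(smiles, collapse = "\n"))
}

test_that("SMILES and InChI tables parse with id/name preserved", {
  p <- write_smiles_tsv(data.frame(id = "x1", name = "ethanol",
                                   smiles = "CCO"))
  rec <- parse_structures(p, "smiles", "demo")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$record_id, "x1")
  expect_equal(rec$structure, "CCO")

  pi <- tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tinchi",
               "y1\tethanol\tInChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3"), pi)
  ri <- parse_structures(pi, "inchi", "demo")
  expect_equal(ri$structure, "CCO")
})

test_that("corrupt entries are skipped with a warning, not fatal", {
  smis <- c("CCO", "CCC", "CCCC", "CCCCC")
  txt <- paste0(sdf_text(smis),
                "corrupt\n\n\n  2  1  0\nJUNK\n$$$$\n")
  f <- tempfile(fileext = ".sdf")
  writeLines(txt, f)
  expect_warning(rec <- parse_structures(f, "sdf", "demo"),
                 "1 unparsable entry skipped")
  expect_equal(nrow(rec), 4L)
  expect_equal(attr(rec, "n_skipped"), 1L)

  # all-corrupt input is fatal with a diagnostic
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tsmiles", "b1\tbad\tnotasmiles(("), f2)
  expect_error(suppressWarnings(parse_structures(f2, "smiles", "demo")),
               "no parsable records")
  expect_error(parse_structures(tempfile(), "smiles", "demo"), "not found")
})

test_that("components split on covalent connectivity in canonical order", {
  expect_length(split_components("CC(=O)[O-].[Na+]"), 2L)
  expect_equal(split_components("CCO"), "CCO")
  expect_length(
    split_components("[Cl-].[Cl-].C[N+](C)(C)CC[N+](C)(C)C"), 3L)
  expect_error(split_components("C1CC(xx"), "does not parse")
})

test_that("the largest component represents the record, ties broken lexically", {
  comps <- split_components("CC(=O)[O-].[Na+]")
  rep <- select_representative(comps)
  expect_match(rep, "O-")  # acetate (MW 59.04) beats sodium (22.99)
  expect_equal(select_representative("CCO"), "CCO")
  expect_equal(select_representative(c("CCO", "CCO")), "CCO")
  expect_equal(select_representative(c("OCC", "CCO")),
               sort(c(split_components("OCC"), "CCO"))[1])
  expect_error(select_representative(character(0)), "no components")
})

test_that("InChIKey skeletons collapse protonation states and stereoisomers", {
  expect_equal(compute_skeleton("CC(=O)O"), "QTBSBXVTEAMEQO")
  expect_equal(compute_skeleton("CC(=O)[O-]"), "QTBSBXVTEAMEQO")
  glc <- "OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@@H]1O"
  gal <- "OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@H]1O"
  expect_equal(compute_skeleton(glc), compute_skeleton(gal))
  expect_equal(compute_skeleton(glc), "WQZGKKKJIJFFOK")
  expect_match(compute_skeleton("C[N+](C)(C)C"), "^[A-Z]{14}$")
})

test_that("normalize_record composes the full pipeline", {
  salt <- normalize_record("CC(=O)[O-].[Na+]", "db", "s1", "sodium acetate")
  expect_equal(salt$skeleton, "QTBSBXVTEAMEQO")
  expect_equal(salt$neutral_formula, "C2H4O2")
  expect_true(salt$is_fragmented)
  expect_equal(salt$original_charge, -1L)
  expect_equal(salt$neutral_monoisotopic_mass, 60.021129,
               tolerance = 5e-6)

  tma <- normalize_record("C[N+](C)(C)C", "db", "c1")
  expect_equal(tma$neutral_formula, "C4H11N")
  expect_equal(tma$neutral_monoisotopic_mass, 73.089149, tolerance = 5e-6)
  expect_equal(tma$original_charge, 1L)
  expect_false(tma$is_fragmented)

  glc <- normalize_record("OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@@H]1O",
                          "db", "g1")
  expect_equal(glc$original_charge, 0L)
  expect_false(glc$is_fragmented)
  expect_equal(glc$neutral_monoisotopic_mass,
               glc$original_ionic_monoisotopic_mass)
  expect_equal(glc$flag, "")

  bare <- normalize_record("[Na+]", "db", "m1")
  expect_equal(bare$flag, "non_neutralizable")
  bad <- normalize_record("C1CC(xx", "db", "b1")
  expect_equal(bad$flag, "parse_error")

  # zwitterions with net charge zero get no hydrogen adjustment
  bet <- normalize_record("C[N+](C)(C)CC([O-])=O", "db", "z1")
  expect_equal(bet$original_charge, 0L)
  expect_equal(bet$neutral_formula, "C5H11NO2")
})

test_that("acid/conjugate-base pairs normalize identically", {
  pairs <- list(
    c("CC(=O)O", "CC(=O)[O-]"),
    c("OC(=O)c1ccccc1", "[O-]C(=O)c1ccccc1"),
    c("OS(O)(=O)=O", "OS([O-])(=O)=O"),
    c("CCC(=O)O", "CCC(=O)[O-]"))
  for (p in pairs) {
    a <- normalize_record(p[1], "db", "a")
    b <- normalize_record(p[2], "db", "b")
    expect_equal(a$skeleton, b$skeleton)
    expect_equal(a$neutral_formula, b$neutral_formula)
    expect_equal(a$neutral_monoisotopic_mass, b$neutral_monoisotopic_mass,
                 tolerance = 1e-9)
  }
})

test_that("normalized entries obey mass and hydrogen bookkeeping", {
  store <- fixture_store()
  ent <- store$entries
  # neutral mass recomputed from the formula agrees with the stored value
  recomp <- vapply(ent$neutral_formula, function(f) {
    unname(compute_masses(f)[["monoisotopic"]])
  }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(abs(recomp - ent$neutral_monoisotopic_mass) < 5e-4))
  # neutralized mass = ionic mass - charge * proton, exactly
  p <- uc2_constants()[["proton_mass"]]
  expect_true(all(abs(
    ent$neutral_monoisotopic_mass -
      (ent$original_ionic_monoisotopic_mass - ent$original_charge * p))
    < 1e-9))
  expect_true(all(grepl("^[A-Z]{14}$", ent$skeleton)))
})

test_that("normalization is a pure function of the structure string", {
  a <- normalize_record("[Cl-].C[N+](C)(C)CCO", "db", "r", "choline chloride")
  b <- normalize_record("[Cl-].C[N+](C)(C)CCO", "db", "r", "choline chloride")
  expect_identical(a, b)
})

test_that("the normalized-entry writer produces the documented columns", {
  ent <- normalize_records(data.frame(
    db_name = "demo", record_id = c("r1", "r2"), name = c("a", "b"),
    structure = c("CCO", "C[N+](C)(C)C"), stringsAsFactors = FALSE))
  f <- tempfile(fileext = ".tsv")
  write_normalized(ent, f)
  back <- utils::read.delim(f, colClasses = "character")
  expect_equal(names(back),
               c("db_name", "record_id", "name", "skeleton",
                 "neutral_formula", "neutral_monoisotopic_mass",
                 "neutral_average_mass", "original_charge",
                 "original_ionic_monoisotopic_mass", "is_fragmented",
                 "flag"))
  expect_match(back$neutral_monoisotopic_mass[1], "^[0-9]+\\.[0-9]{6}$")
})
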