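# Deterministic synthetic compound collections with ground-truth manifests.
# Every expectation in the manifest (skeleton, neutralized formula and mass,
# registered ionic mass) is frozen from the generating recipe -- computed
# with an independent structure toolkit when the template set was curated --
# so that verifying a built store against the manifest is a genuine oracle
# test, not a self-comparison.

.fixture_categories <- c("neutral", "stereo-family", "cation", "anion",
                         "salt", "cross-db-duplicate", "decoy-cation",
                         "decoy-anion", "decoy-raw-mz", "error-structure")

.corrupt_smiles <- c("C1CC(xx", "notasmiles((", "[Zz]Q1=")

#' Curated fixture compound templates
#'
#' A small set of real small molecules -- sugars, organic acids, amino
#' acids, purines, quaternary ammonium and pyridinium cations, sulfonate
#' and sulfate anions, salts, a hydrate, stereoisomer families and
#' cross-database duplicates -- emulating the registration variants found
#' in public compound databases.  Expected skeletons, neutralized formulas
#' and masses are frozen reference values.  Decoy categories exist to
#' construct query m/z values that only the conventional dual search can
#' (falsely) match.
#'
#' @return Data frame with one row per plantable record.
#' @export
uc2_templates <- function() {
  data.frame(
    name = c("ethanol", "acetic acid", "propionic acid", "butyric acid", "valeric acid", "hexanoic acid", "benzoic acid", "salicylic acid", "citric acid", "succinic acid", "fumaric acid", "caffeine", "tryptophan", "phenylalanine", "tyrosine", "uracil", "betaine", "alpha-D-glucose", "alpha-D-galactose", "alpha-D-mannose", "L-tartaric acid", "D-tartaric acid", "meso-tartaric acid", "tetramethylammonium", "tetraethylammonium", "N-methylpyridinium", "choline", "acetylcholine", "sodium cation", "methanesulfonate", "ethanesulfonate", "benzenesulfonate", "p-toluenesulfonate", "hydrogen sulfate", "sodium acetate", "choline chloride", "tetramethylammonium chloride", "sodium methanesulfonate", "glucose monohydrate", "alpha-D-glucose", "caffeine", "tetramethylammonium", "trimethylhexylammonium", "butanesulfonate", "decanoic acid", "adenine", "dodecanoic acid"),
    category = c("neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "neutral", "stereo-family", "stereo-family", "stereo-family", "stereo-family", "stereo-family", "stereo-family", "cation", "cation", "cation", "cation", "cation", "cation", "anion", "anion", "anion", "anion", "anion", "salt", "salt", "salt", "salt", "salt", "cross-db-duplicate", "cross-db-duplicate", "cross-db-duplicate", "decoy-cation", "decoy-anion", "decoy-raw-mz", "decoy-raw-mz", "decoy-raw-mz"),
    smiles = c("CCO", "CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "CCCCC(=O)O", "CCCCCC(=O)O", "OC(=O)c1ccccc1", "OC(=O)c1ccccc1O", "OC(=O)CC(O)(CC(O)=O)C(O)=O", "OC(=O)CCC(O)=O", "OC(=O)/C=C/C(O)=O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "NC(Cc1c[nH]c2ccccc12)C(O)=O", "NC(Cc1ccccc1)C(O)=O", "NC(Cc1ccc(O)cc1)C(O)=O", "O=c1cc[nH]c(=O)[nH]1", "C[N+](C)(C)CC([O-])=O", "OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@@H]1O", "OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@H]1O", "OC[C@H]1O[C@H](O)[C@@H](O)[C@@H](O)[C@@H]1O", "O[C@@H]([C@H](O)C(O)=O)C(O)=O", "O[C@H]([C@@H](O)C(O)=O)C(O)=O", "O[C@H]([C@H](O)C(O)=O)C(O)=O", "C[N+](C)(C)C", "CC[N+](CC)(CC)CC", "C[n+]1ccccc1", "C[N+](C)(C)CCO", "CC(=O)OCC[N+](C)(C)C", "[Na+]", "CS([O-])(=O)=O", "CCS([O-])(=O)=O", "[O-]S(=O)(=O)c1ccccc1", "Cc1ccc(cc1)S([O-])(=O)=O", "OS([O-])(=O)=O", "CC(=O)[O-].[Na+]", "[Cl-].C[N+](C)(C)CCO", "[Cl-].C[N+](C)(C)C", "CS([O-])(=O)=O.[Na+]", "O.OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@@H]1O", "OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@@H]1O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "C[N+](C)(C)C", "CCCCCC[N+](C)(C)C", "CCCCS([O-])(=O)=O", "CCCCCCCCCC(=O)O", "Nc1ncnc2[nH]cnc12", "CCCCCCCCCCCC(=O)O"),
    family = c("", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "hexose", "hexose", "hexose", "tartrate", "tartrate", "tartrate", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "hexose", "", "", "", "", "", "", ""),
    skeleton = c("LFQSCWFLJHTTHZ", "QTBSBXVTEAMEQO", "XBDQKXXYIPTUBI", "FERIUCNNQQJTOY", "NQPDZGIKBAWPEJ", "FUZZWVXGSFPDMH", "WPYMKLBDIGXBTP", "YGSDEFSMJLZEOE", "KRKNYBCHXYNGOX", "KDYFGRWQOYBRFD", "VZCYOOQTPOCHFL", "RYYVLZVUVIJVGH", "QIVBCDIJIAJPQS", "COLNVLDHVKWLRT", "OUYCCCASQSFEME", "ISAKRJDGNUQOIC", "KWIUHFFTVRNATP", "WQZGKKKJIJFFOK", "WQZGKKKJIJFFOK", "WQZGKKKJIJFFOK", "FEWJPZIEWOKRBE", "FEWJPZIEWOKRBE", "FEWJPZIEWOKRBE", "QEMXHQIAXOOASZ", "CBXCPBUEXACCNR", "PQBAWAQIRZIWIV", "OEYIOHPDSNJKLS", "OIPILFWXSMYKGL", "FKNQFGJONOIPTF", "AFVFQIVMOAPDHO", "CCIVGXIOQKPBKL", "SRSXLGNVWSONIS", "JOXIMZWYDAKGHI", "QAOWNCQODCNURD", "QTBSBXVTEAMEQO", "OEYIOHPDSNJKLS", "QEMXHQIAXOOASZ", "AFVFQIVMOAPDHO", "WQZGKKKJIJFFOK", "WQZGKKKJIJFFOK", "RYYVLZVUVIJVGH", "QEMXHQIAXOOASZ", "XTPRURKTXNFVQT", "QDHFHIQKOVNCNC", "GHVNFZFCNZKVNT", "GFFGJBXGBJISGV", "POULHZVOKOAJMA"),
    neutral_formula = c("C2H6O", "C2H4O2", "C3H6O2", "C4H8O2", "C5H10O2", "C6H12O2", "C7H6O2", "C7H6O3", "C6H8O7", "C4H6O4", "C4H4O4", "C8H10N4O2", "C11H12N2O2", "C9H11NO2", "C9H11NO3", "C4H4N2O2", "C5H11NO2", "C6H12O6", "C6H12O6", "C6H12O6", "C4H6O6", "C4H6O6", "C4H6O6", "C4H11N", "C8H19N", "C6H7N", "C5H13NO", "C7H15NO2", "", "CH4O3S", "C2H6O3S", "C6H6O3S", "C7H8O3S", "H2O4S", "C2H4O2", "C5H13NO", "C4H11N", "CH4O3S", "C6H12O6", "C6H12O6", "C8H10N4O2", "C4H11N", "C9H21N", "C4H10O3S", "C10H20O2", "C5H5N5", "C12H24O2"),
    neutral_monoisotopic_mass = c(46.041864812, 60.021129368, 74.036779432, 88.052429496, 102.068079560, 116.083729624, 122.036779432, 138.031694052, 192.027002596, 118.026608672, 116.010958608, 194.080375560, 204.089877624, 165.078978592, 181.073893212, 112.027277368, 117.078978592, 180.063388104, 180.063388104, 180.063388104, 150.016437912, 150.016437912, 150.016437912, 73.089149352, 129.151749608, 93.057849224, 103.099714036, 145.110278720, NA_real_, 95.988114988, 110.003765052, 158.003765052, 172.019415116, 97.967379544, 60.021129368, 103.099714036, 73.089149352, 95.988114988, 180.063388104, 180.063388104, 194.080375560, 73.089149352, 143.167399672, 138.035065180, 172.146329880, 135.054495160, 200.177630008),
    original_charge = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, -1, -1, -1, -1, -1, -1, 1, 1, -1, 0, 0, 0, 1, 1, -1, 0, 0, 0),
    original_ionic_monoisotopic_mass = c(46.041864812, 60.021129368, 74.036779432, 88.052429496, 102.068079560, 116.083729624, 122.036779432, 138.031694052, 192.027002596, 118.026608672, 116.010958608, 194.080375560, 204.089877624, 165.078978592, 181.073893212, 112.027277368, 117.078978592, 180.063388104, 180.063388104, 180.063388104, 150.016437912, 150.016437912, 150.016437912, 74.096425804, 130.159026060, 94.065125676, 104.106990488, 146.117555172, 22.989220700, 94.980838536, 108.996488600, 156.996488600, 171.012138664, 96.960103092, 59.013852916, 104.106990488, 74.096425804, 94.980838536, 180.063388104, 180.063388104, 194.080375560, 74.096425804, 144.174676124, 137.027788728, 172.146329880, 135.054495160, 200.177630008),
    is_fragmented = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    flag = c("", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "non_neutralizable", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", "", ""),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic compound collection with a ground-truth manifest
#'
#' Writes two pseudo-database SMILES tables (`alpha.tsv`, `beta.tsv`;
#' cross-database duplicates go to `beta`), optionally salted with corrupt
#' rows (`error-structure`), and a JSON manifest recording every planted
#' record's expected skeleton, neutralized formula and masses, charge and
#' fragmentation state, plus the decoy constructions (which query m/z each
#' decoy is built to falsely match, and via which baseline route).  Output
#' is byte-identical for a fixed seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param counts Named integer vector of records per category; defaults to
#'   the full curated set per category and 2 corrupt rows.  Requests beyond
#'   the curated template capacity raise an error naming the category.
#' @param seed Integer seed (controls record order and id assignment).
#' @return The manifest, invisibly (list with `db_files`, `items`,
#'   `decoys`, `n_distinct_skeletons`).
#' @export
generate_collection <- function(out_dir, counts = NULL, seed = 1L) {
  tpl <- uc2_templates()
  avail <- table(factor(tpl$category, levels = .fixture_categories))
  avail[["error-structure"]] <- length(.corrupt_smiles)
  default <- as.integer(avail)
  names(default) <- names(avail)
  default[["error-structure"]] <- 2L
  if (is.null(counts)) counts <- default
  full <- default
  full[names(counts)] <- counts
  counts <- full
  if (all(counts == 0L)) stop("at least one category must be nonzero",
                              call. = FALSE)
  for (cat in names(counts)) {
    if (counts[[cat]] > avail[[cat]]) {
      stop("requested ", counts[[cat]], " '", cat, "' entries but only ",
           avail[[cat]], " templates are curated", call. = FALSE)
    }
  }
  picked <- do.call(rbind, lapply(.fixture_categories, function(cat) {
    if (cat == "error-structure") return(NULL)
    rows <- tpl[tpl$category == cat, , drop = FALSE]
    utils::head(rows, counts[[cat]])
  }))
  picked$db <- ifelse(picked$category == "cross-db-duplicate",
                      "beta", "alpha")
  n_err <- counts[["error-structure"]]
  if (n_err > 0L) {
    err <- data.frame(name = paste0("corrupt entry ",
                                    seq_len(n_err)),
                      category = "error-structure",
                      smiles = .corrupt_smiles[seq_len(n_err)],
                      family = "", skeleton = NA_character_,
                      neutral_formula = NA_character_,
                      neutral_monoisotopic_mass = NA_real_,
                      original_charge = NA_integer_,
                      original_ionic_monoisotopic_mass = NA_real_,
                      is_fragmented = NA, flag = "error_structure",
                      db = "alpha", stringsAsFactors = FALSE)
    picked <- rbind(picked, err)
  }
  # deterministic per-seed shuffle within each pseudo-database, then ids
  items <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(c("alpha", "beta"), function(db) {
      r <- picked[picked$db == db, , drop = FALSE]
      if (nrow(r) == 0L) return(NULL)
      r <- r[sample.int(nrow(r)), , drop = FALSE]
      r$record_id <- sprintf("%s%03d", toupper(substr(db, 1, 1)),
                             seq_len(nrow(r)))
      r
    }))
  })
  rownames(items) <- NULL
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  db_files <- character(0)
  for (db in unique(items$db)) {
    r <- items[items$db == db, , drop = FALSE]
    path <- file.path(out_dir, paste0(db, ".tsv"))
    utils::write.table(
      data.frame(id = r$record_id, name = r$name, smiles = r$smiles,
                 stringsAsFactors = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    db_files[db] <- path
  }
  p <- .uc2_proton_mass
  dec <- items[grepl("^decoy-", items$category), , drop = FALSE]
  decoys <- data.frame(
    name = dec$name, db = dec$db, record_id = dec$record_id,
    category = dec$category,
    mode = ifelse(dec$category == "decoy-cation", "positive",
                  ifelse(dec$category == "decoy-anion", "negative",
                         ifelse(dec$original_ionic_monoisotopic_mass > 190,
                                "negative", "positive"))),
    route = ifelse(dec$category == "decoy-raw-mz", "raw-mz",
                   "neutral-mass"),
    stringsAsFactors = FALSE)
  decoys$trigger_mz <- ifelse(
    decoys$route == "raw-mz", dec$original_ionic_monoisotopic_mass,
    ifelse(decoys$mode == "positive",
           dec$original_ionic_monoisotopic_mass + p,
           dec$original_ionic_monoisotopic_mass - p))
  ok <- items$flag == "" & !is.na(items$skeleton)
  # manifest.json keeps basenames so output is byte-identical across
  # directories; the returned manifest carries resolved paths
  manifest_disk <- list(
    db_files = as.list(basename(db_files)),
    seed = as.integer(seed),
    items = items[, c("db", "record_id", "name", "smiles", "category",
                      "family", "skeleton", "neutral_formula",
                      "neutral_monoisotopic_mass", "original_charge",
                      "original_ionic_monoisotopic_mass", "is_fragmented",
                      "flag")],
    decoys = decoys,
    n_distinct_skeletons = length(unique(items$skeleton[ok])))
  jsonlite::write_json(manifest_disk, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  manifest <- manifest_disk
  manifest$db_files <- as.list(db_files)
  invisible(manifest)
}

#' Read a manifest written by [generate_collection()]
#'
#' @param path Path to `manifest.json` or its directory.
#' @return Manifest list.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- jsonlite::fromJSON(path)
  m$db_files <- lapply(m$db_files, function(f) {
    file.path(dirname(path), basename(f))
  })
  m$items <- as.data.frame(m$items, stringsAsFactors = FALSE)
  m$items$flag[is.na(m$items$flag)] <- ""
  m$decoys <- as.data.frame(m$decoys, stringsAsFactors = FALSE)
  m
}

# Recipe-level expectation for one query: which search(es) should hit,
# computed by brute force over the manifest's frozen masses only.
.expected_found_in <- function(mz, mode, items, tol) {
  p <- .uc2_proton_mass
  M <- if (mode == "positive") mz - p else mz + p
  within <- function(center, masses) {
    win <- tolerance_window(center, tol)
    !is.na(masses) & masses >= win[["lo"]] & masses <= win[["hi"]]
  }
  ok <- items$flag == ""
  uc2_hit <- within(M, items$neutral_monoisotopic_mass) & ok
  conv_hit <- (within(M, items$original_ionic_monoisotopic_mass) |
                 within(mz, items$original_ionic_monoisotopic_mass)) & ok
  found <- if (any(uc2_hit) && any(conv_hit)) "both"
  else if (any(uc2_hit)) "only_uc2"
  else if (any(conv_hit)) "only_conventional"
  else "neither"
  cls <- "n/a"
  if (found == "only_uc2") {
    cls <- if (any(items$original_charge[uc2_hit] != 0L |
                     items$is_fragmented[uc2_hit])) "true_positive"
    else "false_positive"
  } else if (found == "only_conventional") {
    cls <- "false_positive"
  }
  list(found_in = found, classification = cls)
}

#' Generate a peak list with per-peak ground truth
#'
#' Emits one peak per planted target at its theoretical ion m/z (adduct ion
#' for uncharged entries in both modes, molecular ion for charged entries
#' in their own polarity, and an additional negative-mode peak at ionic
#' mass minus two protons for each +1 entry, emulating pigment cations
#' detected as [M-2H]- ions), plus the decoy trigger peaks and peaks in
#' empty mass regions.  The truth table gives each peak's expected
#' `found_in` and classification, derived by brute force from the
#' manifest's frozen masses.  Decoy constructions are checked: a decoy
#' trigger that would not come out conventional-only raises an error naming
#' the conflicting constraint.
#'
#' @param manifest Manifest from [generate_collection()].
#' @param out_dir Optional directory for `peaks.tsv` / `truth.tsv`.
#' @param jitter_ppm Uniform m/z jitter half-width in ppm (default 0:
#'   exact theoretical peaks); keep below the search tolerance.
#' @param seed Integer seed for the jitter draws.
#' @param tol `uc2_tolerance` the truth is computed under.
#' @return List with `peaks` and `truth` data frames.
#' @export
generate_peaks <- function(manifest, out_dir = NULL, jitter_ppm = 0,
                           seed = 1L, tol = mass_tolerance(5, "ppm")) {
  items <- manifest$items
  decoys <- manifest$decoys
  p <- .uc2_proton_mass
  tgt <- items[items$flag == "" & !grepl("^decoy-", items$category), ,
               drop = FALSE]
  peaks <- list()
  add <- function(mz, mode, ref) {
    peaks[[length(peaks) + 1L]] <<- data.frame(
      mz = mz, mode = mode, ref = ref, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tgt))) {
    q <- tgt$original_charge[i]
    ion <- tgt$original_ionic_monoisotopic_mass[i]
    if (q == 0L) {
      add(ion + p, "positive", tgt$name[i])
      add(ion - p, "negative", tgt$name[i])
    } else if (q > 0L) {
      add(ion, "positive", tgt$name[i])
      add(ion - 2 * p, "negative", paste0(tgt$name[i], " [M-2H]-"))
    } else {
      add(ion, "negative", tgt$name[i])
    }
  }
  for (i in seq_len(nrow(decoys))) {
    add(decoys$trigger_mz[i], decoys$mode[i],
        paste0("decoy trigger: ", decoys$name[i]))
  }
  # empty-region peaks: far from every planted mass
  add(399.9001, "positive", "empty region")
  add(650.4002, "positive", "empty region")
  add(410.1003, "negative", "empty region")
  add(701.2004, "negative", "empty region")
  pk <- do.call(rbind, peaks)
  pk <- pk[!duplicated(data.frame(round(pk$mz, 6), pk$mode)), ,
           drop = FALSE]
  truth <- lapply(seq_len(nrow(pk)), function(i) {
    e <- .expected_found_in(pk$mz[i], pk$mode[i], items, tol)
    data.frame(found_in = e$found_in, classification = e$classification,
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, truth)
  for (i in seq_len(nrow(decoys))) {
    j <- which(abs(pk$mz - decoys$trigger_mz[i]) < 1e-9 &
                 pk$mode == decoys$mode[i])
    if (!length(j) || truth$found_in[j[1]] != "only_conventional") {
      stop("decoy construction failed for '", decoys$name[i],
           "': trigger m/z ", format(decoys$trigger_mz[i]),
           " (", decoys$mode[i], ") is not conventional-only under ",
           tol$value, " ", tol$unit, call. = FALSE)
    }
  }
  if (jitter_ppm > 0) {
    jit <- withr::with_seed(as.integer(seed),
                            stats::runif(nrow(pk), -jitter_ppm, jitter_ppm))
    pk$mz <- pk$mz * (1 + jit * 1e-6)
  }
  pk$peak_id <- sprintf("p%03d", seq_len(nrow(pk)))
  peaks_df <- pk[, c("peak_id", "mz", "mode")]
  truth_df <- cbind(pk[, "peak_id", drop = FALSE], truth,
                    ref = pk$ref, stringsAsFactors = FALSE)
  rownames(peaks_df) <- rownames(truth_df) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pw <- peaks_df
    pw$mz <- sprintf("%.6f", pw$mz)
    utils::write.table(pw, file.path(out_dir, "peaks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth_df, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(peaks = peaks_df, truth = truth_df)
}

#' Verify a built store against a fixture manifest
#'
#' Checks every planted item's expectations against the store: accepted
#' items must sit in the group keyed by their expected skeleton, with the
#' expected neutralized formula and a neutralized monoisotopic mass within
#' 5e-4 Da; flagged and corrupt items must be absent from the searchable
#' members.  The group count must equal the manifest's distinct-skeleton
#' count.
#'
#' @param store `uc2_store` built from the fixture files.
#' @param manifest Manifest from [generate_collection()].
#' @return Data frame report (one row per check) with attribute `ok`;
#'   `attr(report, "ok")` is `TRUE` iff every check passed.
#' @export
verify_manifest <- function(store, manifest) {
  items <- manifest$items
  checks <- list()
  note <- function(item, check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      item = item, check = check, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  mem_key <- paste(store$members$db_name, store$members$record_id)
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    label <- paste0(it$db, ":", it$record_id, " ", it$name)
    if (it$flag != "") {
      note(label, "absent_from_index",
           !(paste(it$db, it$record_id) %in% mem_key))
      next
    }
    grp <- tryCatch(query_by_skeleton(store, it$skeleton),
                    error = function(e) NULL)
    if (is.null(grp)) {
      note(label, "skeleton_present", FALSE,
           paste0("no group ", it$skeleton))
      next
    }
    note(label, "skeleton_present", TRUE)
    note(label, "membership",
         any(grp$members$db_name == it$db &
               grp$members$record_id == it$record_id))
    note(label, "neutral_formula",
         it$neutral_formula %in% grp$group$neutral_formula,
         paste0("want ", it$neutral_formula))
    note(label, "neutral_mass",
         any(abs(grp$group$neutral_monoisotopic_mass -
                   it$neutral_monoisotopic_mass) <= 5e-4))
    j <- which(grp$members$db_name == it$db &
                 grp$members$record_id == it$record_id)
    if (length(j)) {
      note(label, "charge_signature",
           grp$members$original_charge[j[1]] == it$original_charge)
      note(label, "fragmented_flag",
           grp$members$is_fragmented[j[1]] == it$is_fragmented)
    }
  }
  note("store", "group_count",
       nrow(store$groups) == manifest$n_distinct_skeletons,
       paste0(nrow(store$groups), " vs ",
              manifest$n_distinct_skeletons))
  report <- do.call(rbind, checks)
  attr(report, "ok") <- all(report$pass)
  report
}

#' Build a store directly from fixture files
#'
#' Convenience wrapper: parse both pseudo-databases, normalize and build.
#'
#' @param manifest Manifest from [generate_collection()].
#' @return `uc2_store`.
#' @export
build_fixture_store <- function(manifest) {
  recs <- do.call(rbind, lapply(names(manifest$db_files), function(db) {
    suppressWarnings(
      parse_structures(manifest$db_files[[db]], "smiles", db))
  }))
  build_store(normalize_records(recs))
}
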