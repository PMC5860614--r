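# Record normalization: readers for the three input dialects, and the
# record -> normalized-entry pipeline (component split, representative
# selection, tentative neutralization, skeleton and mass computation).

.norm_cols <- c("db_name", "record_id", "name", "skeleton", "neutral_formula",
                "neutral_monoisotopic_mass", "neutral_average_mass",
                "original_charge", "original_ionic_monoisotopic_mass",
                "is_fragmented", "flag")

#' Read a compound collection into source records
#'
#' Supported dialects: SDF (V2000 molblocks, record id taken from the title
#' line), and tab-separated tables `id<TAB>name<TAB>smiles` or
#' `id<TAB>name<TAB>inchi` with a header row.  Every entry is parsed and
#' canonicalized on read; unparsable entries are skipped with a warning and
#' counted in the `n_skipped` attribute.
#'
#' @param path Input file path.
#' @param format `"sdf"`, `"smiles"` or `"inchi"`.
#' @param db_name Short label of the source collection.
#' @return Data frame with columns `db_name`, `record_id`, `name`,
#'   `structure` (canonical SMILES); attribute `n_skipped` counts skipped
#'   entries.
#' @export
parse_structures <- function(path, format = c("sdf", "smiles", "inchi"),
                             db_name) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFstr(path)
    chunks <- sdf@a
    ids <- vapply(chunks, function(x) trimws(x[1]), "")
    raw <- vapply(chunks, function(x) paste(x, collapse = "\n"), "")
    nm <- ids
    can <- vapply(raw, .canonical_smiles, "", format = "molblock",
                  USE.NAMES = FALSE)
    ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    want <- c("id", "name", if (format == "smiles") "smiles" else "inchi")
    if (!all(want %in% names(tab))) {
      stop("TSV must have columns ", paste(want, collapse = ", "),
           call. = FALSE)
    }
    ids <- tab$id
    nm <- tab$name
    can <- vapply(tab[[want[3]]], .canonical_smiles, "",
                  format = if (format == "smiles") "smiles" else "inchi",
                  USE.NAMES = FALSE)
  }
  keep <- !is.na(can) & nzchar(can)
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(n_skipped, " unparsable entr",
            if (n_skipped == 1L) "y" else "ies", " skipped in ", path,
            call. = FALSE)
  }
  if (!any(keep)) {
    stop("no parsable records in ", path, " (", length(keep), " entries, ",
         n_skipped, " skipped)", call. = FALSE)
  }
  out <- data.frame(db_name = db_name, record_id = ids[keep],
                    name = nm[keep], structure = can[keep],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$record_id)) {
    stop("duplicate record ids within ", db_name, call. = FALSE)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Normalize one source record
#'
#' Pipeline: split into components, keep the largest as representative,
#' record its net charge and registered (electron-corrected) ionic mass,
#' neutralize the formula by hydrogen adjustment, compute neutralized
#' masses, and compute the InChIKey skeleton of the representative as
#' registered.  Failures do not raise: the returned row carries a reason
#' code in `flag` (`"parse_error"`, `"non_neutralizable"`,
#' `"inchi_failure"`) and flagged rows are excluded from mass indexes while
#' staying in provenance output.
#'
#' @param structure Structure string.
#' @param db_name,record_id,name Provenance fields.
#' @param format Input dialect of `structure`.
#' @return One-row data frame with the normalized-entry columns.
#' @export
normalize_record <- function(structure, db_name = "db", record_id = "r1",
                             name = "", format = "smiles") {
  row <- data.frame(db_name = db_name, record_id = record_id, name = name,
                    skeleton = NA_character_,
                    neutral_formula = NA_character_,
                    neutral_monoisotopic_mass = NA_real_,
                    neutral_average_mass = NA_real_,
                    original_charge = NA_integer_,
                    original_ionic_monoisotopic_mass = NA_real_,
                    is_fragmented = NA, flag = "",
                    stringsAsFactors = FALSE)
  comps <- tryCatch(split_components(structure, format),
                    error = function(e) NULL)
  if (is.null(comps)) {
    row$flag <- "parse_error"
    return(row)
  }
  row$is_fragmented <- length(comps) > 1L
  rep_smi <- select_representative(comps)
  q <- .smiles_net_charge(rep_smi)
  fml <- .smiles_formula(rep_smi)
  if (is.na(fml)) {
    row$flag <- "parse_error"
    return(row)
  }
  row$original_charge <- q
  reg <- compute_masses(fml)
  row$original_ionic_monoisotopic_mass <-
    unname(reg[["monoisotopic"]]) - q * .uc2_electron_mass
  neutral <- suppressWarnings(neutralize_formula(fml, q))
  skel <- compute_skeleton(rep_smi)
  row$skeleton <- skel
  if (is.na(neutral)) {
    row$flag <- "non_neutralizable"
    return(row)
  }
  nm <- compute_masses(neutral)
  row$neutral_formula <- neutral
  row$neutral_monoisotopic_mass <- unname(nm[["monoisotopic"]])
  row$neutral_average_mass <- unname(nm[["average"]])
  if (is.na(skel)) {
    row$flag <- "inchi_failure"
  }
  row
}

#' Normalize a table of source records
#'
#' @param records Data frame as returned by [parse_structures()].
#' @return Data frame of normalized entries, one row per input record.
#' @export
normalize_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("db_name", "record_id", "structure") %in% names(records)))
  nm <- if ("name" %in% names(records)) records$name else ""
  rows <- lapply(seq_len(nrow(records)), function(i) {
    normalize_record(records$structure[i], records$db_name[i],
                     records$record_id[i], nm[i])
  })
  do.call(rbind, rows)
}

#' Write normalized entries as TSV
#'
#' Masses are written as fixed 6-decimal text.
#'
#' @param entries Normalized-entry data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(entries, path) {
  out <- entries[, .norm_cols]
  for (col in c("neutral_monoisotopic_mass", "neutral_average_mass",
                "original_ionic_monoisotopic_mass")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.6f", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
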