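# The UC2 store: normalized entries grouped by InChIKey skeleton, with a
# mass-ordered index over neutralized monoisotopic masses and secondary
# exact-match lookups on skeleton and formula.  Members keep their
# as-registered ionic masses so the conventional-search baseline can be
# emulated from the same artifact.

.store_key <- function(skeleton, formula) paste(skeleton, formula, sep = "|")

#' Build a UC2 store from normalized entries
#'
#' One group per distinct InChIKey skeleton among accepted (unflagged)
#' entries; stereoisomers, protonation states and cross-database duplicates
#' of one connectivity collapse into a single group.  Should two entries
#' share a skeleton but disagree on neutralized formula (exotic charge
#' states), the groups are split by (skeleton, formula) and a warning is
#' raised.  Flagged entries are kept in `$rejected` for provenance but take
#' no part in queries.
#'
#' @param entries Normalized-entry data frame ([normalize_records()]).
#' @return Object of class `uc2_store`.
#' @export
build_store <- function(entries) {
  stopifnot(is.data.frame(entries), all(.norm_cols %in% names(entries)))
  entries <- entries[, .norm_cols]
  ok <- entries$flag == "" & !is.na(entries$skeleton)
  acc <- entries[ok, , drop = FALSE]
  # idempotent on provenance: one membership per (db, id) and skeleton
  acc <- acc[!duplicated(acc[, c("db_name", "record_id", "skeleton")]), ,
             drop = FALSE]
  key <- .store_key(acc$skeleton, acc$neutral_formula)
  if (nrow(acc) > 0L) {
    per_skel <- tapply(acc$neutral_formula, acc$skeleton,
                       function(x) length(unique(x)))
    if (any(per_skel > 1L)) {
      warning("skeleton(s) with conflicting neutral formulas split by ",
              "(skeleton, formula): ",
              paste(names(per_skel)[per_skel > 1L], collapse = ", "),
              call. = FALSE)
    }
  }
  ukey <- unique(key)
  first <- match(ukey, key)
  groups <- data.frame(
    group_id = seq_along(ukey),
    skeleton = acc$skeleton[first],
    neutral_formula = acc$neutral_formula[first],
    neutral_monoisotopic_mass = acc$neutral_monoisotopic_mass[first],
    neutral_average_mass = acc$neutral_average_mass[first],
    stringsAsFactors = FALSE)
  ord <- order(groups$neutral_monoisotopic_mass, groups$skeleton)
  groups <- groups[ord, , drop = FALSE]
  groups$group_id <- seq_len(nrow(groups))
  rownames(groups) <- NULL
  members <- acc[, c("db_name", "record_id", "name", "original_charge",
                     "original_ionic_monoisotopic_mass", "is_fragmented")]
  members <- cbind(
    group_id = groups$group_id[match(key, .store_key(groups$skeleton,
                                                     groups$neutral_formula))],
    members)
  members <- members[order(members$group_id, members$db_name,
                           members$record_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(groups = groups, members = members,
                 entries = acc[order(acc$db_name, acc$record_id), ,
                               drop = FALSE],
                 rejected = entries[!ok, , drop = FALSE]),
            class = "uc2_store")
}

#' @export
print.uc2_store <- function(x, ...) {
  cat("uc2_store:", nrow(x$groups), "groups,", nrow(x$members),
      "members,", nrow(x$rejected), "rejected entries\n")
  invisible(x)
}

#' Insert or update one normalized entry
#'
#' Appends the entry to its skeleton's group, creating the group when
#' absent.  Idempotent for an identical (db_name, record_id): re-inserting
#' leaves the store unchanged.  Because R objects are copied on modify, the
#' updated store is returned (fetch the affected group with
#' [query_by_skeleton()]).
#'
#' @param store `uc2_store`.
#' @param entry One-row normalized-entry data frame (unflagged).
#' @return Updated `uc2_store`.
#' @export
upsert_entry <- function(store, entry) {
  stopifnot(inherits(store, "uc2_store"), is.data.frame(entry),
            nrow(entry) == 1L)
  if (entry$flag != "" || is.na(entry$skeleton)) {
    stop("cannot upsert a flagged entry (flag = '", entry$flag, "')",
         call. = FALSE)
  }
  build_store(rbind(store$entries, entry[, .norm_cols], store$rejected))
}

#' Mass-window query
#'
#' Returns the groups whose indexed mass lies in `[lo, hi]` (boundaries
#' inclusive), ordered by distance from the window center.  With
#' `mass_kind = "original_ionic"` the window is applied to members'
#' as-registered ionic masses instead (baseline emulation) and groups with
#' at least one matching member are returned.
#'
#' @param store `uc2_store`.
#' @param lo,hi Window bounds in Da, `lo <= hi`.
#' @param mass_kind `"neutral"` (default) or `"original_ionic"`.
#' @return Data frame of matching group rows.
#' @export
query_mass_window <- function(store, lo, hi,
                              mass_kind = c("neutral", "original_ionic")) {
  stopifnot(inherits(store, "uc2_store"))
  mass_kind <- match.arg(mass_kind)
  if (lo > hi) stop("lo > hi", call. = FALSE)
  if (mass_kind == "neutral") {
    g <- store$groups
    hit <- g[g$neutral_monoisotopic_mass >= lo &
             g$neutral_monoisotopic_mass <= hi, , drop = FALSE]
    dist <- abs(hit$neutral_monoisotopic_mass - (lo + hi) / 2)
  } else {
    m <- store$members
    sel <- m$original_ionic_monoisotopic_mass >= lo &
      m$original_ionic_monoisotopic_mass <= hi
    ids <- unique(m$group_id[sel])
    g <- store$groups
    hit <- g[g$group_id %in% ids, , drop = FALSE]
    best <- vapply(hit$group_id, function(id) {
      mm <- m$original_ionic_monoisotopic_mass[sel & m$group_id == id]
      min(abs(mm - (lo + hi) / 2))
    }, numeric(1))
    dist <- best
  }
  out <- hit[order(dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact lookup by InChIKey skeleton
#'
#' @param store `uc2_store`.
#' @param skeleton 14-character uppercase key.
#' @return List with `group` (one-row data frame) and `members`, or `NULL`
#'   when the key is absent.
#' @export
query_by_skeleton <- function(store, skeleton) {
  stopifnot(inherits(store, "uc2_store"))
  if (!is.character(skeleton) || length(skeleton) != 1L ||
      !grepl("^[A-Z]{14}$", skeleton)) {
    stop("malformed skeleton key (want 14 uppercase letters): '",
         skeleton, "'", call. = FALSE)
  }
  g <- store$groups[store$groups$skeleton == skeleton, , drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  m <- store$members[store$members$group_id %in% g$group_id, , drop = FALSE]
  rownames(g) <- rownames(m) <- NULL
  structure(list(group = g, members = m), class = "uc2_group")
}

#' Exact lookup by neutralized formula
#'
#' The query is canonicalized to Hill order first, so any element-order
#' spelling of the same composition matches.
#'
#' @param store `uc2_store`.
#' @param formula Formula string or named count vector.
#' @return Data frame of matching group rows (possibly empty): all
#'   constitutional isomer skeletons sharing that composition.
#' @export
query_by_formula <- function(store, formula) {
  stopifnot(inherits(store, "uc2_store"))
  f <- format_formula(formula)
  out <- store$groups[store$groups$neutral_formula %in% f, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export / load a store as TSV
#'
#' One row per member with the group columns repeated; masses as fixed
#' 6-decimal text.  `load_store(export_store(x))` answers every query with
#' the same groups and members.
#'
#' @param store `uc2_store`.
#' @param path File path.
#' @return `export_store`: `path` invisibly; `load_store`: a `uc2_store`.
#' @export
export_store <- function(store, path) {
  stopifnot(inherits(store, "uc2_store"))
  ent <- rbind(store$entries, store$rejected)
  ent <- ent[order(ent$db_name, ent$record_id), , drop = FALSE]
  gid <- store$members$group_id[
    match(paste(ent$db_name, ent$record_id),
          paste(store$members$db_name, store$members$record_id))]
  out <- cbind(group_id = ifelse(is.na(gid), "", gid), ent)
  for (col in c("neutral_monoisotopic_mass", "neutral_average_mass",
                "original_ionic_monoisotopic_mass")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.6f", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_store
#' @export
load_store <- function(path) {
  if (!file.exists(path)) stop("store file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("malformed store file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(c("group_id", .norm_cols), names(tab))
  if (length(missing)) {
    stop("malformed store file ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), " (line 1)", call. = FALSE)
  }
  bad <- which(is.na(tab$db_name) | is.na(tab$record_id))
  if (length(bad)) {
    stop("malformed store file ", path, ": incomplete row at line ",
         bad[1] + 1L, call. = FALSE)
  }
  ent <- tab[, .norm_cols]
  for (col in c("neutral_monoisotopic_mass", "neutral_average_mass",
                "original_ionic_monoisotopic_mass")) {
    ent[[col]] <- suppressWarnings(as.numeric(ent[[col]]))
  }
  ent$original_charge <- suppressWarnings(as.integer(ent$original_charge))
  ent$is_fragmented <- as.logical(ent$is_fragmented)
  ent$flag[is.na(ent$flag)] <- ""
  ent$name[is.na(ent$name)] <- ""
  ent$skeleton[is.na(ent$skeleton)] <- NA_character_
  build_store(ent)
}
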