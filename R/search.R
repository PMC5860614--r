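# The two search semantics.  The single-query search converts the observed
# m/z to a hypothetical neutral mass per assumed adduct and matches it
# against neutralized masses, so charged registrations (whose neutralized
# mass differs from their ionic mass by exactly one proton per charge) are
# found by the same query as uncharged ones.  The conventional baseline
# reproduces the dual strategy it replaces: default-adduct neutral-mass
# lookup plus raw-m/z lookup, both against as-registered masses, counted per
# record without skeleton deduplication.

.hit_cols <- function() {
  data.frame(group_id = integer(0), skeleton = character(0),
             neutral_formula = character(0),
             neutral_monoisotopic_mass = numeric(0),
             adduct = character(0), matched_mass = numeric(0),
             error_ppm = numeric(0), charge_mismatch = character(0),
             baseline_route = character(0), stringsAsFactors = FALSE)
}

# Charge/polarity consistency of a set of member charges under one polarity.
.charge_flag <- function(charges, polarity) {
  charges <- charges[!is.na(charges)]
  if (!length(charges) || all(charges == 0L)) return("none")
  if (polarity == "positive") {
    if (any(charges > 0L)) "charged-entry-positive-mode"
    else "negative-entry-positive-mode"
  } else {
    if (any(charges > 0L)) "positive-entry-negative-mode"
    else "charged-entry-negative-mode"
  }
}

#' Annotate a hit with its charge-consistency flag
#'
#' The registered charge signature of a group's members is compared with the
#' polarity of the assumed adduct.  A charged entry matched in its own
#' polarity is flagged as a molecular-ion interpretation; a positively
#' charged entry matched in negative mode is flagged but kept, since such
#' ions (e.g. flavylium pigments) are genuinely observed as [M-2H]- ions.
#' Flags are informational and never remove a hit.
#'
#' @param hit One-row hit data frame (from [uc2_search()]).
#' @param adduct `uc2_adduct` or registry name assumed for the hit.
#' @param store The queried `uc2_store` (for member charges).
#' @return The hit row with `charge_mismatch` set to one of `"none"`,
#'   `"charged-entry-positive-mode"`, `"charged-entry-negative-mode"`,
#'   `"positive-entry-negative-mode"`, `"negative-entry-positive-mode"`.
#' @export
flag_charge_mismatch <- function(hit, adduct, store) {
  a <- .as_adducts(adduct)[[1]]
  m <- store$members[store$members$group_id == hit$group_id, , drop = FALSE]
  hit$charge_mismatch <- .charge_flag(m$original_charge, a$polarity)
  hit
}

#' Single-query accurate-mass search over neutralized masses
#'
#' For each assumed adduct the observed m/z is converted to a neutral mass
#' and matched, within tolerance, against the neutralized monoisotopic
#' masses of the store groups.  Because a +1 registration's neutralized mass
#' is its ionic mass minus one proton, its molecular ion [M]+ is found by
#' the default [M+H]+ assumption in the same query as any uncharged
#' compound (and symmetrically for anions under [M-H]-).  One hit per
#' (group, adduct); each hit carries a charge-consistency flag.
#'
#' @param store `uc2_store`.
#' @param mz Observed m/z.
#' @param adducts Adduct names or `uc2_adduct` list, all of one polarity.
#' @param tol `uc2_tolerance` (default 5 ppm).
#' @return Hit data frame, ordered by absolute mass error.
#' @export
uc2_search <- function(store, mz, adducts, tol = mass_tolerance(5, "ppm")) {
  stopifnot(inherits(store, "uc2_store"), is.numeric(mz), length(mz) == 1L)
  adducts <- .as_adducts(adducts)
  if (length(adducts) == 0L) stop("empty adduct list", call. = FALSE)
  pol <- unique(vapply(adducts, `[[`, "", "polarity"))
  if (length(pol) != 1L) {
    stop("adducts must share one polarity", call. = FALSE)
  }
  out <- .hit_cols()
  for (a in adducts) {
    M <- neutral_mass_from_mz(mz, a)
    win <- tolerance_window(M, tol)
    g <- query_mass_window(store, win[["lo"]], win[["hi"]], "neutral")
    if (nrow(g) == 0L) next
    hits <- data.frame(
      group_id = g$group_id, skeleton = g$skeleton,
      neutral_formula = g$neutral_formula,
      neutral_monoisotopic_mass = g$neutral_monoisotopic_mass,
      adduct = a$name, matched_mass = g$neutral_monoisotopic_mass,
      error_ppm = (M - g$neutral_monoisotopic_mass) /
        g$neutral_monoisotopic_mass * 1e6,
      charge_mismatch = vapply(g$group_id, function(id) {
        m <- store$members[store$members$group_id == id, , drop = FALSE]
        .charge_flag(m$original_charge, a$polarity)
      }, ""),
      baseline_route = "n/a", stringsAsFactors = FALSE)
    out <- rbind(out, hits)
  }
  out <- out[!duplicated(out[, c("group_id", "adduct")]), , drop = FALSE]
  out <- out[order(abs(out$error_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conventional dual-search baseline
#'
#' Union of (a) the neutral-mass route: records whose as-registered
#' monoisotopic mass (ionic for charged entries) matches the neutral mass
#' implied by the default adduct, and (b) the raw-m/z route: records whose
#' as-registered mass matches the observed m/z itself.  Candidates are
#' counted per record; no skeleton deduplication is applied.  This is the
#' strategy whose union of routes admits the false positives the
#' neutralized single-query search avoids.
#'
#' @param store `uc2_store`.
#' @param mz Observed m/z.
#' @param default_adduct Adduct name or `uc2_adduct`; its polarity must
#'   match the acquisition mode of the query.
#' @param tol `uc2_tolerance`.
#' @return Data frame with one row per (record, route): `db_name`,
#'   `record_id`, `name`, `skeleton`, `group_id`, `registered_mass`,
#'   `original_charge`, `is_fragmented`, `baseline_route` in
#'   `{"neutral-mass", "raw-mz"}`, `error_ppm`.
#' @export
conventional_search <- function(store, mz, default_adduct,
                                tol = mass_tolerance(5, "ppm")) {
  stopifnot(inherits(store, "uc2_store"), is.numeric(mz), length(mz) == 1L)
  a <- .as_adducts(default_adduct)[[1]]
  m <- store$members
  targets <- list(
    c(route = "neutral-mass", center = neutral_mass_from_mz(mz, a)),
    c(route = "raw-mz", center = mz))
  rows <- lapply(targets, function(t) {
    center <- as.numeric(t[["center"]])
    win <- tolerance_window(center, tol)
    sel <- !is.na(m$original_ionic_monoisotopic_mass) &
      m$original_ionic_monoisotopic_mass >= win[["lo"]] &
      m$original_ionic_monoisotopic_mass <= win[["hi"]]
    if (!any(sel)) return(NULL)
    hit <- m[sel, , drop = FALSE]
    g <- store$groups
    data.frame(
      db_name = hit$db_name, record_id = hit$record_id, name = hit$name,
      skeleton = g$skeleton[match(hit$group_id, g$group_id)],
      group_id = hit$group_id,
      registered_mass = hit$original_ionic_monoisotopic_mass,
      original_charge = hit$original_charge,
      is_fragmented = hit$is_fragmented,
      baseline_route = t[["route"]],
      error_ppm = (center - hit$original_ionic_monoisotopic_mass) /
        hit$original_ionic_monoisotopic_mass * 1e6,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(db_name = character(0), record_id = character(0),
                      name = character(0), skeleton = character(0),
                      group_id = integer(0), registered_mass = numeric(0),
                      original_charge = integer(0),
                      is_fragmented = logical(0),
                      baseline_route = character(0),
                      error_ppm = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
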