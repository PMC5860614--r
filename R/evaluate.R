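# Benchmark harness: run both search semantics over a peak list, tally
# exclusive results, classify them, and compute candidate-count statistics.

.default_adducts <- c(positive = "[M+H]+", negative = "[M-H]-")

#' Run the single-query and conventional searches over a peak list
#'
#' For every peak both searches are executed with the mode's default adduct
#' (and optionally further adducts for the single-query search).  Each peak
#' is assigned to `both`, `only_uc2`, `only_conventional` or `neither` by
#' non-emptiness of the two result sets; exclusive peaks are classified by
#' [classify_exclusive()].
#'
#' @param peaks Data frame with columns `peak_id`, `mz`, `mode`
#'   (`"positive"`/`"negative"`).
#' @param store `uc2_store`.
#' @param adducts Named list (by mode) of adduct-name vectors for the
#'   single-query search; defaults to the default adduct of each mode.
#' @param default_adducts Named character vector (by mode) of the baseline's
#'   default adduct.
#' @param tol `uc2_tolerance`.
#' @return List with `rows` (one row per peak: counts, found_in,
#'   classification, joined hit keys) and `summary` (see
#'   [summarize_comparison()]).
#' @export
compare_searches <- function(peaks, store,
                             adducts = NULL,
                             default_adducts = .default_adducts,
                             tol = mass_tolerance(5, "ppm")) {
  stopifnot(is.data.frame(peaks),
            all(c("peak_id", "mz", "mode") %in% names(peaks)))
  if (nrow(peaks) == 0L) stop("empty peak list", call. = FALSE)
  stopifnot(all(peaks$mode %in% c("positive", "negative")),
            all(peaks$mz > 0))
  if (is.null(adducts)) {
    adducts <- list(positive = default_adducts[["positive"]],
                    negative = default_adducts[["negative"]])
  }
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    mode <- peaks$mode[i]
    u <- uc2_search(store, peaks$mz[i], adducts[[mode]], tol)
    cv <- conventional_search(store, peaks$mz[i],
                              default_adducts[[mode]], tol)
    conv_ids <- unique(paste(cv$db_name, cv$record_id, sep = ":"))
    found_in <- if (nrow(u) && length(conv_ids)) "both"
    else if (nrow(u)) "only_uc2"
    else if (length(conv_ids)) "only_conventional"
    else "neither"
    data.frame(peak_id = peaks$peak_id[i], mz = peaks$mz[i], mode = mode,
               n_uc2 = length(unique(u$group_id)),
               n_conv = length(conv_ids),
               uc2_groups = paste(sort(unique(u$skeleton)), collapse = ";"),
               conv_records = paste(sort(conv_ids), collapse = ";"),
               found_in = found_in, classification = "n/a",
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  rows <- classify_exclusive(rows, store,
                             default_adducts = default_adducts, tol = tol)
  list(rows = rows, summary = summarize_comparison(rows))
}

#' Classify exclusive results as true or false positives
#'
#' Peaks found only by the single-query search are true positives when at
#' least one hit group contains a charged or fragmented member (the cases
#' the neutralized index exists to recover) and false positives otherwise.
#' Peaks found only by the conventional baseline are false positives when
#' their exclusive records are charged entries reached through the
#' neutral-mass or raw-m/z routes -- the baseline's characteristic failure
#' mode -- and are otherwise left unclassified as `"n/a"`.
#'
#' @param rows Row table from [compare_searches()].
#' @param store `uc2_store`.
#' @param default_adducts,tol As in [compare_searches()].
#' @return `rows` with the `classification` column filled in.
#' @export
classify_exclusive <- function(rows, store,
                               default_adducts = .default_adducts,
                               tol = mass_tolerance(5, "ppm")) {
  for (i in seq_len(nrow(rows))) {
    if (rows$found_in[i] == "only_uc2") {
      skels <- strsplit(rows$uc2_groups[i], ";", fixed = TRUE)[[1]]
      special <- any(vapply(skels, function(s) {
        grp <- query_by_skeleton(store, s)
        !is.null(grp) && any(grp$members$original_charge != 0L |
                               grp$members$is_fragmented)
      }, TRUE))
      rows$classification[i] <- if (special) "true_positive"
      else "false_positive"
    } else if (rows$found_in[i] == "only_conventional") {
      cv <- conventional_search(store, rows$mz[i],
                                default_adducts[[rows$mode[i]]], tol)
      charged <- any(cv$original_charge != 0L)
      rows$classification[i] <- if (charged || nrow(cv) > 0L)
        "false_positive" else "n/a"
    }
  }
  rows
}

#' Tabulate the comparison
#'
#' Per mode and overall: query and hit counts, exclusive counts with
#' percentages (denominator: peaks with a result in either search, reported
#' to 1 decimal place), true/false-positive tallies of the exclusive rows,
#' and candidate-count statistics.
#'
#' @param rows Row table from [compare_searches()].
#' @return Data frame with one row per mode plus `"all"`.
#' @export
summarize_comparison <- function(rows) {
  one <- function(r, label) {
    found <- sum(r$found_in != "neither")
    only_c <- sum(r$found_in == "only_conventional")
    only_u <- sum(r$found_in == "only_uc2")
    stats <- candidate_stats(r)
    data.frame(
      mode = label, queries = nrow(r), results_found = found,
      found_conventional = sum(r$found_in %in%
                                 c("both", "only_conventional")),
      found_uc2 = sum(r$found_in %in% c("both", "only_uc2")),
      only_conventional = only_c,
      only_conventional_pct = if (found) round(100 * only_c / found, 1)
      else NA_real_,
      only_uc2 = only_u,
      only_uc2_pct = if (found) round(100 * only_u / found, 1)
      else NA_real_,
      true_positives = sum(r$classification == "true_positive"),
      false_positives = sum(r$classification == "false_positive"),
      fraction_fewer = stats[["fraction_fewer"]],
      fraction_single = stats[["fraction_single"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("positive", "negative"), function(mode) {
    r <- rows[rows$mode == mode, , drop = FALSE]
    if (nrow(r) == 0L) NULL else one(r, mode)
  }))
  rbind(out, one(rows, "all"))
}

#' Candidate-count statistics
#'
#' Among peaks with a result in either search: the fraction whose
#' single-query candidate count (groups) is smaller than the baseline count
#' (records), and the fraction with exactly one single-query candidate.
#'
#' @param rows Row table from [compare_searches()].
#' @return Named numeric `c(fraction_fewer = , fraction_single = )`; `NA`
#'   when no peak has results.
#' @export
candidate_stats <- function(rows) {
  r <- rows[rows$found_in != "neither", , drop = FALSE]
  if (nrow(r) == 0L) {
    return(c(fraction_fewer = NA_real_, fraction_single = NA_real_))
  }
  c(fraction_fewer = mean(r$n_uc2 < r$n_conv),
    fraction_single = mean(r$n_uc2 == 1L))
}

#' Random m/z queries
#'
#' Uniform draws over a mass range, reproducible for a fixed seed; the
#' design probes how often arbitrary masses pick up (false) hits in each
#' search.
#'
#' @param n Number of queries (>= 1).
#' @param mass_range `c(lo, hi)` m/z bounds, `lo < hi`.
#' @param mode `"positive"` or `"negative"`.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return Peak data frame (`peak_id`, `mz`, `mode`).
#' @export
random_mass_queries <- function(n, mass_range = c(100, 1500),
                                mode = c("positive", "negative"), seed) {
  mode <- match.arg(mode)
  stopifnot(n >= 1L, length(mass_range) == 2L)
  if (mass_range[1] >= mass_range[2]) {
    stop("invalid mass range: lo must be < hi", call. = FALSE)
  }
  mz <- withr::with_seed(as.integer(seed),
                         stats::runif(n, mass_range[1], mass_range[2]))
  data.frame(peak_id = sprintf("rand_%s_%05d", substr(mode, 1, 3),
                               seq_len(n)),
             mz = mz, mode = mode, stringsAsFactors = FALSE)
}
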