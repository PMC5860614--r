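# Elemental composition arithmetic: parsing, Hill formatting, hydrogen-based
# charge neutralization and formula masses.  Masses are computed from a fixed
# element table (most-abundant-isotope masses and standard atomic weights) so
# that neutralized formulas -- which have no corresponding structure object --
# get the same treatment as registered ones.

.uc2_elements <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al", "Si", "P", "S", "Cl", "K", "Ca", "Ti", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "As", "Se", "Br", "Mo", "Ag", "Cd", "Sn", "Sb", "I", "Ba", "W", "Pt", "Au", "Hg", "Pb"),
  monoisotopic = c(1.007825032, 4.002603254, 7.016004550, 9.012182200, 11.009305400, 12.000000000, 14.003074000, 15.994914620, 18.998403220, 19.992440180, 22.989769280, 23.985041700, 26.981538630, 27.976926530, 30.973761630, 31.972071000, 34.968852680, 38.963706680, 39.962590980, 47.947946300, 51.940507500, 54.938045100, 55.934937500, 58.933195000, 57.935342900, 62.929597500, 63.929142200, 74.921596500, 79.916521300, 78.918337100, 97.905408200, 106.905097000, 113.903358500, 119.902194700, 120.903815700, 126.904473000, 137.905247200, 183.950931200, 194.964791100, 196.966568700, 201.970643000, 207.976652100),
  average = c(1.008000, 4.003000, 6.941000, 9.012000, 10.812000, 12.011000, 14.007000, 15.999000, 18.998000, 20.180000, 22.990000, 24.305000, 26.982000, 28.086000, 30.974000, 32.067000, 35.453000, 39.098000, 40.078000, 47.867000, 51.996000, 54.938000, 55.845000, 58.933000, 58.693000, 63.546000, 65.390000, 74.922000, 78.960000, 79.904000, 95.940000, 107.868000, 112.412000, 118.711000, 121.760000, 126.904000, 137.328000, 183.840000, 195.078000, 196.967000, 200.590000, 207.200000),
  stringsAsFactors = FALSE
)

# CODATA electron mass; proton mass is derived from the H atom so that
# ionic-mass bookkeeping is exactly self-consistent in double precision.
.uc2_electron_mass <- 0.00054857990907
.uc2_proton_mass <- 1.007825032 - 0.00054857990907

#' Physical constants used in ion-mass arithmetic
#'
#' @return Named numeric vector with `electron_mass` and `proton_mass` in Da.
#'   The proton mass equals the monoisotopic hydrogen-atom mass minus the
#'   electron mass, so that neutralization and adduct arithmetic cancel
#'   exactly.
#' @export
uc2_constants <- function() {
  c(electron_mass = .uc2_electron_mass, proton_mass = .uc2_proton_mass)
}

#' Parse a molecular formula string into element counts
#'
#' Accepts plain formulas such as `"C6H12O6"`.  A trailing charge decoration
#' (`"+"`, `"-"`, `"++"`, `"+2"`) as emitted by structure toolkits is
#' tolerated and ignored.  Repeated element symbols are summed.
#'
#' @param formula A single formula string, or an already-parsed named numeric
#'   vector of element counts (returned unchanged).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(formula[formula > 0])
  }
  stopifnot(is.character(formula), length(formula) == 1L)
  f <- sub("[+-]+[0-9]*$", "", trimws(formula))
  if (!nzchar(f)) {
    stop("empty formula", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  tokens <- regmatches(f, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(f)) {
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.integer(ifelse(grepl("[0-9]$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(syms, .uc2_elements$symbol)
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(cnts, syms, sum)
  out <- as.vector(counts)
  names(out) <- names(counts)
  out[out > 0]
}

#' Format element counts as a Hill-order formula string
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; without
#' carbon all elements (including H) are alphabetical.
#'
#' @param counts Named numeric vector of element counts, or a formula string
#'   (re-canonicalized).
#' @return Single formula string in Hill order.
#' @examples
#' format_formula(c(O = 2, C = 2, H = 4))  # "C2H4O2"
#' @export
format_formula <- function(counts) {
  counts <- parse_formula(counts)
  syms <- names(counts)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  paste0(ord, ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}

#' Tentatively neutralize a formula by hydrogen adjustment
#'
#' Removes `net_charge` hydrogens from a cationic composition or adds
#' `|net_charge|` hydrogens to an anionic one, leaving all other element
#' counts unchanged.  This is a formula-level bookkeeping device, not a
#' chemical transformation: it gives charged and uncharged registrations a
#' common mass scale for single-query searching.
#'
#' @param formula Formula string or named count vector (composition of the
#'   species as registered, without charge decoration).
#' @param net_charge Signed integer net charge of the species.
#' @return Hill-order formula string of the neutralized composition, or
#'   `NA_character_` (with a warning) when a positive charge exceeds the
#'   available hydrogens, e.g. a bare metal cation.
#' @examples
#' neutralize_formula("C4H12N", 1)   # "C4H11N"
#' neutralize_formula("C2H3O2", -1)  # "C2H4O2"
#' @export
neutralize_formula <- function(formula, net_charge) {
  counts <- parse_formula(formula)
  net_charge <- as.integer(net_charge)
  if (net_charge == 0L) {
    return(format_formula(counts))
  }
  h <- if ("H" %in% names(counts)) counts[["H"]] else 0L
  if (h - net_charge < 0L) {
    warning("cannot neutralize '", format_formula(counts), "' (charge ",
            net_charge, "): not enough hydrogens", call. = FALSE)
    return(NA_character_)
  }
  counts["H"] <- h - net_charge
  format_formula(counts)
}

#' Monoisotopic and average mass of a formula
#'
#' Monoisotopic mass sums the most-abundant-isotope mass of each element;
#' average mass sums standard atomic weights.  Electron mass is not included
#' (apply it separately for ionic species).
#'
#' @param formula Formula string or named count vector.
#' @return Named numeric vector `c(monoisotopic = , average = )` in Da.
#' @examples
#' compute_masses("C6H12O6")
#' @export
compute_masses <- function(formula) {
  counts <- parse_formula(formula)
  idx <- match(names(counts), .uc2_elements$symbol)
  c(monoisotopic = sum(counts * .uc2_elements$monoisotopic[idx]),
    average = sum(counts * .uc2_elements$average[idx]))
}
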