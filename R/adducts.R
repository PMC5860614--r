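# Adduct-ion mass arithmetic.  An adduct maps a neutral monoisotopic mass M
# to m/z = (n*M + delta)/z, with the electron mass folded into delta, so a
# molecular ion [M]+ is simply delta = -electron_mass.

.adduct_registry <- function() {
  p <- .uc2_proton_mass
  e <- .uc2_electron_mass
  na <- 22.989769280 - e
  k <- 38.963706680 - e
  nh4 <- 14.003074000 + 4 * 1.007825032 - e
  cl <- 34.968852680 + e
  h2o <- 2 * 1.007825032 + 15.994914620
  specs <- list(
    list("[M+H]+",     "positive", 1L, 1L,  p),
    list("[M-H]-",     "negative", 1L, 1L, -p),
    list("[M]+",       "positive", 1L, 1L, -e),
    list("[M]-",       "negative", 1L, 1L,  e),
    list("[M+Na]+",    "positive", 1L, 1L,  na),
    list("[M+K]+",     "positive", 1L, 1L,  k),
    list("[M+NH4]+",   "positive", 1L, 1L,  nh4),
    list("[M+Cl]-",    "negative", 1L, 1L,  cl),
    list("[M-H2O+H]+", "positive", 1L, 1L,  p - h2o),
    list("[M-2H]-",    "negative", 1L, 1L, -(p + 1.007825032)),
    list("[M+2H]2+",   "positive", 2L, 1L,  2 * p),
    list("[M-2H]2-",   "negative", 2L, 1L, -2 * p),
    list("[2M+H]+",    "positive", 1L, 2L,  p),
    list("[2M-H]-",    "negative", 1L, 2L, -p)
  )
  out <- lapply(specs, function(s) {
    adduct_spec(s[[1]], s[[2]], z = s[[3]], n = s[[4]], delta = s[[5]])
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Construct an adduct-ion specification
#'
#' @param name Display label, e.g. `"[M+H]+"`.
#' @param polarity `"positive"` or `"negative"`.
#' @param z Charge magnitude (>= 1).
#' @param n Molecule multiplicity (>= 1).
#' @param delta Mass offset in Da such that m/z = (n*M + delta)/z; the
#'   electron mass is folded into `delta`.
#' @return List of class `uc2_adduct`.
#' @export
adduct_spec <- function(name, polarity = c("positive", "negative"),
                        z = 1L, n = 1L, delta) {
  polarity <- match.arg(polarity)
  stopifnot(z >= 1L, n >= 1L, is.numeric(delta))
  structure(list(name = name, polarity = polarity, z = as.integer(z),
                 n = as.integer(n), delta = delta), class = "uc2_adduct")
}

#' Built-in adduct registry
#'
#' @param names Optional character vector selecting entries; unknown names
#'   raise an error.  Default adducts in practice are `"[M+H]+"` (positive
#'   mode) and `"[M-H]-"` (negative mode).
#' @return Named list of `uc2_adduct` objects.
#' @export
uc2_adducts <- function(names = NULL) {
  reg <- .adduct_registry()
  if (is.null(names)) return(reg)
  bad <- setdiff(names, base::names(reg))
  if (length(bad)) {
    stop("unknown adduct(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  reg[names]
}

.as_adducts <- function(adducts) {
  if (inherits(adducts, "uc2_adduct")) return(list(adducts))
  if (is.character(adducts)) return(uc2_adducts(adducts))
  stopifnot(is.list(adducts), all(vapply(adducts, inherits, TRUE,
                                         "uc2_adduct")))
  adducts
}

#' Mass tolerance specification
#'
#' @param value Positive tolerance value.
#' @param unit `"ppm"` (relative) or `"mDa"` (absolute).
#' @return List of class `uc2_tolerance`.
#' @export
mass_tolerance <- function(value = 5, unit = c("ppm", "mDa")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(value), value > 0)
  structure(list(value = value, unit = unit), class = "uc2_tolerance")
}

#' m/z of an adduct ion from a neutral mass
#'
#' @param M Neutral monoisotopic mass in Da (> 0).
#' @param adduct `uc2_adduct` or registry name.
#' @return m/z value.
#' @examples
#' mz_from_neutral_mass(180.063388, "[M+H]+")
#' @export
mz_from_neutral_mass <- function(M, adduct) {
  a <- .as_adducts(adduct)[[1]]
  stopifnot(all(M > 0))
  (a$n * M + a$delta) / a$z
}

#' Neutral mass from an observed m/z under an assumed adduct
#'
#' Exact algebraic inverse of [mz_from_neutral_mass()].
#'
#' @param mz Observed m/z (> 0).
#' @param adduct `uc2_adduct` or registry name.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass_from_mz <- function(mz, adduct) {
  a <- .as_adducts(adduct)[[1]]
  stopifnot(all(mz > 0))
  M <- (mz * a$z - a$delta) / a$n
  if (any(M <= 0)) {
    stop("non-positive neutral mass: adduct ", a$name,
         " is nonsensical for m/z ", format(mz), call. = FALSE)
  }
  M
}

#' Tolerance window around a mass or m/z
#'
#' @param center Center value (> 0).
#' @param tol `uc2_tolerance`.
#' @return Numeric `c(lo, hi)`; ppm windows scale with `center`, mDa windows
#'   are absolute.
#' @examples
#' tolerance_window(100, mass_tolerance(10, "ppm"))
#' @export
tolerance_window <- function(center, tol) {
  stopifnot(inherits(tol, "uc2_tolerance"), center > 0)
  half <- if (tol$unit == "ppm") center * tol$value * 1e-6 else
    tol$value * 1e-3
  c(lo = center - half, hi = center + half)
}
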