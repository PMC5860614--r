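# Structure toolkit layer.  All parsing, canonicalization and InChIKey
# generation goes through Open Babel (ChemmineOB); formula/charge bookkeeping
# on top is done here.  Conversions are per-record so that a malformed entry
# never aborts a batch: failures come back as NA and are flagged upstream.

.ob_convert <- function(from, to, text) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, text),
    error = function(e) ""
  )
  out <- trimws(out)
  if (!nzchar(out)) NA_character_ else out
}

# Canonical SMILES of one record; `format` tags the input dialect.
.canonical_smiles <- function(structure, format = c("smiles", "inchi", "molblock")) {
  format <- match.arg(format)
  from <- c(smiles = "SMI", inchi = "INCHI", molblock = "SDF")[[format]]
  out <- .ob_convert(from, "CAN", structure)
  if (is.na(out)) return(NA_character_)
  # OB appends the title after a tab
  sub("\t.*$", "", out)
}

.inchikey <- function(smiles) {
  out <- .ob_convert("SMI", "INCHIKEY", smiles)
  if (is.na(out)) return(NA_character_)
  strsplit(out, "[ \t\n]")[[1]][1]
}

# Net formal charge of a SMILES string, read from its bracket atoms.
# Handles [O-], [N+], [Mg+2], [Mg++], [Fe+3] and repeated-sign spellings.
.smiles_net_charge <- function(smiles) {
  m <- gregexpr("\\[[^]]*\\]", smiles)[[1]]
  if (m[1] == -1L) return(0L)
  total <- 0L
  for (br in regmatches(smiles, list(m))[[1]]) {
    cm <- gregexpr("([+-])([0-9]+)?", br)[[1]]
    if (cm[1] == -1L) next
    toks <- regmatches(br, list(cm))[[1]]
    for (tk in toks) {
      sign <- if (substr(tk, 1, 1) == "+") 1L else -1L
      num <- sub("^[+-]", "", tk)
      total <- total + sign * (if (nzchar(num)) as.integer(num) else 1L)
    }
  }
  total
}

# Molecular formula (charge decoration stripped) of one single-component
# SMILES, as assigned by the toolkit (implicit hydrogens included).
.smiles_formula <- function(smiles) {
  mols <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, identity),
    error = function(e) NULL
  )
  if (is.null(mols) || length(mols) == 0L) return(NA_character_)
  p <- tryCatch(ChemmineOB::prop_OB(mols[[1]]), error = function(e) NULL)
  if (is.null(p) || is.null(p$formula) || !nzchar(p$formula)) {
    return(NA_character_)
  }
  sub("[+-]+[0-9]*$", "", p$formula)
}

#' Split a record structure into covalently connected components
#'
#' Components are the dot-separated units of the canonical SMILES; order is
#' the deterministic canonical-output order.
#'
#' @param structure Structure string (SMILES by default).
#' @param format Input dialect: `"smiles"`, `"inchi"` or `"molblock"`.
#' @return Character vector of single-component canonical SMILES.
#' @examples
#' \donttest{split_components("CC(=O)[O-].[Na+]")}
#' @export
split_components <- function(structure, format = "smiles") {
  can <- .canonical_smiles(structure, format)
  if (is.na(can)) {
    stop("structure does not parse: '", structure, "'", call. = FALSE)
  }
  strsplit(can, ".", fixed = TRUE)[[1]]
}

#' Select the representative component of a (possibly fragmented) record
#'
#' The component with the largest average molecular weight represents the
#' record; ties are broken by the lexicographically smallest canonical
#' SMILES so selection is deterministic.
#'
#' @param components Character vector of single-component SMILES (as from
#'   [split_components()]).
#' @return Single SMILES string.
#' @export
select_representative <- function(components) {
  if (length(components) == 0L) {
    stop("no components to select from", call. = FALSE)
  }
  if (length(components) == 1L) return(components[[1]])
  mw <- vapply(components, function(s) {
    f <- .smiles_formula(s)
    if (is.na(f)) return(-Inf)
    unname(compute_masses(f)[["average"]])
  }, numeric(1))
  ord <- order(-mw, components)
  components[[ord[1]]]
}

#' InChIKey skeleton (first block) of a structure
#'
#' The first 14 letters of the standard InChIKey encode atom connectivity
#' only: stereoisomers, isotopologues and protonation states of one skeleton
#' share it.  It is computed on the component as registered, charged forms
#' included (standard InChI normalization handles the protonation layer).
#'
#' @param smiles Single-component SMILES.
#' @return 14-character uppercase string, or `NA_character_` if InChI
#'   generation fails.
#' @examples
#' \donttest{compute_skeleton("CC(=O)O")  # "QTBSBXVTEAMEQO"}
#' @export
compute_skeleton <- function(smiles) {
  key <- .inchikey(smiles)
  if (is.na(key)) return(NA_character_)
  skel <- substr(key, 1, 14)
  if (!grepl("^[A-Z]{14}$", skel)) return(NA_character_)
  skel
}
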