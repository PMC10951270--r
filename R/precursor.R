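#' Parse an elemental formula
#'
#' @param formula String such as `"C2H3NO"` (Hill-ish, elements restricted
#'   to H, C, N, O, S, P; omitted count means 1).
#' @return Named numeric vector over H, C, N, O, S, P.
#' @export
parse_formula <- function(formula) {
  out <- c(H = 0, C = 0, N = 0, O = 0, S = 0, P = 0)
  if (!nzchar(formula)) return(out)
  m <- gregexpr("([HCNOSP])(\\d*)", formula)[[1]]
  pieces <- regmatches(formula, gregexpr("([HCNOSP])(\\d*)", formula))[[1]]
  if (sum(nchar(pieces)) != nchar(formula)) {
    stop("malformed elemental formula: ", formula)
  }
  for (p in pieces) {
    el <- substr(p, 1, 1)
    k <- substr(p, 2, nchar(p))
    out[el] <- out[el] + if (nzchar(k)) as.numeric(k) else 1
  }
  out
}

#' Construct a glycopeptide precursor
#'
#' The unit of prediction: a peptide sequence with optional modifications,
#' a glycosylation site, an N-glycan tree and a precursor charge.
#'
#' @param peptide Peptide string (20 standard one-letter codes).
#' @param glycan A [glycan_tree()] or a structure string.
#' @param glycosite 1-based index of the glycosylated residue.
#' @param charge Precursor charge state (>= 1).
#' @param mods Optional tibble with columns `pos` (1-based residue index)
#'   and `formula` (elemental delta, e.g. `"C2H3NO"` for
#'   carbamidomethylation); a `mass` column is derived.
#' @return A `glycopeptide` object.
#' @examples
#' gp <- glycopeptide("IGSYNGTAGDSLSYHQGR", "(N(N(H(H)(H))))",
#'                    glycosite = 5, charge = 2)
#' @export
glycopeptide <- function(peptide, glycan, glycosite, charge,
                         mods = NULL) {
  if (is.character(glycan)) glycan <- parse_glycan(glycan)
  stopifnot(inherits(glycan, "glycan_tree"))
  aa <- strsplit(peptide, "")[[1]]
  if (!all(aa %in% names(.aa_mass))) {
    stop("unknown amino acid code in peptide: ",
         paste(setdiff(aa, names(.aa_mass)), collapse = ", "))
  }
  glycosite <- as.integer(glycosite)
  if (glycosite < 1L || glycosite > length(aa)) {
    stop("glycosite out of range")
  }
  charge <- as.integer(charge)
  if (charge < 1L) stop("charge must be >= 1")
  if (is.null(mods)) {
    mods <- tibble::tibble(pos = integer(0), formula = character(0),
                           mass = numeric(0))
  } else {
    mods <- tibble::as_tibble(mods)
    stopifnot(all(c("pos", "formula") %in% names(mods)))
    if (any(mods$pos < 1L | mods$pos > length(aa))) {
      stop("modification position out of range")
    }
    mods$mass <- vapply(mods$formula,
                        function(f) .elemental_mass(parse_formula(f)),
                        numeric(1))
  }
  structure(
    list(peptide = peptide, glycan = glycan, glycosite = glycosite,
         charge = charge, mods = mods),
    class = "glycopeptide"
  )
}

#' @export
print.glycopeptide <- function(x, ...) {
  comp <- format_composition(glycan_composition(x$glycan))
  seq <- x$peptide
  cat("<glycopeptide> ",
      substr(seq, 1, x$glycosite - 1), "[", comp, "]",
      substr(seq, x$glycosite, nchar(seq)),
      " ", x$charge, "+\n", sep = "")
  invisible(x)
}

#' Stable identifier of a precursor
#'
#' @param gp A [glycopeptide()].
#' @return A string combining peptide, modifications, glycosite, canonical
#'   glycan structure and charge.
#' @export
precursor_id <- function(gp) {
  modtag <- if (nrow(gp$mods) == 0) "" else
    paste0(";", paste0(gp$mods$pos, ":", gp$mods$formula, collapse = ","))
  paste0(gp$peptide, modtag, "/", gp$glycosite, "/",
         glycan_canonical(gp$glycan), "/", gp$charge)
}

#' Neutral mass and m/z of a glycopeptide precursor
#'
#' @param gp A [glycopeptide()].
#' @return Precursor m/z at the precursor's charge.
#' @export
precursor_mz <- function(gp) {
  m <- peptide_mass(gp$peptide, gp$mods$mass) +
    sum(residue_mass(gp$glycan$code))
  (m + gp$charge * .proton_mass) / gp$charge
}
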