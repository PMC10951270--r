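#' @keywords internal
#' @useDynLib glycospectra, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @importFrom stats predict
"_PACKAGE"

## Monoisotopic atomic masses (CODATA/IUPAC 2021)
.atomic_mass <- c(
  H = 1.0078250319, C = 12.0, N = 14.0030740052,
  O = 15.9949146221, S = 31.97207069, P = 30.97376151
)

.proton_mass <- 1.007276466
.water_mass <- 2 * .atomic_mass[["H"]] + .atomic_mass[["O"]]

.elemental_mass <- function(counts) {
  # counts: named numeric over subset of H,C,N,O,S,P
  sum(.atomic_mass[names(counts)] * counts)
}

## The five monosaccharide classes handled by the model, one-letter codes
## as used in composition strings such as H(5)N(4)F(1)A(2).
.mono_table <- local({
  comp <- list(
    Hex    = c(C = 6, H = 10, O = 5),
    HexNAc = c(C = 8, H = 13, N = 1, O = 5),
    NeuAc  = c(C = 11, H = 17, N = 1, O = 8),
    NeuGc  = c(C = 11, H = 17, N = 1, O = 9),
    Fuc    = c(C = 6, H = 10, O = 4)
  )
  tibble::tibble(
    symbol = names(comp),
    code = c("H", "N", "A", "G", "F"),
    residue_mass = vapply(comp, .elemental_mass, numeric(1))
  )
})

## Canonical code order for rendering compositions: hexose counts first,
## then HexNAc and fucose, sialic acids appended.
.comp_code_order <- c("H", "N", "F", "A", "G")

#' Monosaccharide residue masses
#'
#' Monoisotopic residue (dehydrated) masses of the five monosaccharide
#' classes used throughout the package: hexose (H), N-acetylhexosamine (N),
#' fucose/deoxyhexose (F), N-acetylneuraminic acid (A) and
#' N-glycolylneuraminic acid (G).
#'
#' @param mono Character vector of symbols (`"Hex"`, `"HexNAc"`, `"NeuAc"`,
#'   `"NeuGc"`, `"Fuc"`) or one-letter codes (`"H"`, `"N"`, `"A"`, `"G"`,
#'   `"F"`).
#' @return Numeric vector of monoisotopic residue masses in Da.
#' @examples
#' residue_mass(c("Hex", "HexNAc", "Fuc"))
#' residue_mass("N")
#' @export
residue_mass <- function(mono) {
  idx <- match(mono, .mono_table$symbol)
  idx[is.na(idx)] <- match(mono[is.na(idx)], .mono_table$code)
  if (anyNA(idx)) {
    stop("unknown monosaccharide: ",
         paste(mono[is.na(idx)], collapse = ", "))
  }
  unname(.mono_table$residue_mass[idx])
}

#' Monosaccharide alphabet
#'
#' @return A tibble with columns `symbol`, `code` and `residue_mass`.
#' @export
monosaccharides <- function() .mono_table

## Amino acid monoisotopic residue masses (20 standard residues)
.aa_mass <- c(
  G = 57.02146374, A = 71.03711381, S = 87.03202844, P = 97.05276388,
  V = 99.06841395, T = 101.04767851, C = 103.00918448, L = 113.08406402,
  I = 113.08406402, N = 114.04292747, D = 115.02694306, Q = 128.05857754,
  K = 128.09496305, E = 129.04259313, M = 131.04048463, H = 137.05891188,
  F = 147.06841395, R = 156.10111105, Y = 163.06332858, W = 186.07931298
)

## Cross-ring remnant retained on the peptide for b$/y$ ions: C4H5NO,
## the prevailing 0,2-A convention for GlcNAc in glycoproteomics engines.
.cross_ring_mass <- .elemental_mass(c(C = 4, H = 5, N = 1, O = 1))

#' Peptide monoisotopic mass
#'
#' Neutral monoisotopic mass of a peptide with optional modification mass
#' deltas.
#'
#' @param sequence Single peptide string over the 20 standard one-letter
#'   amino acid codes.
#' @param mod_masses Optional numeric vector of modification mass deltas
#'   (Da), summed onto the peptide.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, mod_masses = numeric()) {
  aa <- strsplit(sequence, "")[[1]]
  m <- .aa_mass[aa]
  if (anyNA(m)) {
    stop("unknown amino acid code: ",
         paste(unique(aa[is.na(m)]), collapse = ", "))
  }
  sum(m) + .water_mass + sum(mod_masses)
}
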