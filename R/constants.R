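#' Monoisotopic mass constants
#'
#' Fixed monoisotopic constants used throughout the fragment-mass model:
#' the proton mass, the mass of one water molecule, and the residue
#' (i.e. dehydrated amino acid) masses of the 20 canonical amino acids.
#' Leucine and isoleucine share a mass and are kept as distinct letters;
#' no disambiguation is attempted.
#'
#' @format `PROTON_MASS` and `WATER_MASS` are single numerics (Da);
#'   `RESIDUE_MASSES` is a named numeric vector over the 20 canonical
#'   one-letter codes (Da).
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
PROTON_MASS <- 1.00727646

#' @rdname mass-constants
#' @export
WATER_MASS <- 18.0105646

#' @rdname mass-constants
#' @export
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
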