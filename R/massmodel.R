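## Core mass arithmetic: residue sums, neutral masses, m/z <-> mass.

.aa_vec <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty amino-acid sequence")
  aa <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!aa %in% names(RESIDUE_MASSES))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1L]], bad[1L]))
  }
  aa
}

#' Sum of monoisotopic residue masses
#'
#' @param seq amino-acid string over the 20 canonical one-letter codes.
#' @return Sum of residue masses in Da (no termini, no water).
#' @examples
#' residue_mass_sum("NAD")
#' @export
residue_mass_sum <- function(seq) {
  sum(RESIDUE_MASSES[.aa_vec(seq)])
}

#' Neutral monoisotopic peptide mass
#'
#' A linear peptide carries one water (H at the N terminus, OH at the C
#' terminus) on top of its residue masses. Macrolactam (lasso) closure
#' condenses the N-terminal alpha-amine with the side-chain carboxyl of
#' the ring acceptor and loses exactly that water, so the lasso form
#' weighs one water less than the linear form of the same sequence.
#'
#' @param seq amino-acid string.
#' @param form `"linear"` or `"lasso"`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' neutral_mass("GG", "linear")
#' neutral_mass("NADGG", "lasso")
#' @export
neutral_mass <- function(seq, form = c("linear", "lasso")) {
  form <- match.arg(form)
  s <- residue_mass_sum(seq)
  if (form == "lasso") {
    if (nchar(seq) < 2L) stop("lasso form requires at least 2 residues")
    s
  } else {
    s + WATER_MASS
  }
}

#' Neutral mass from an observed m/z
#'
#' @param mz observed m/z in Th.
#' @param z positive integer charge (protonation assumed).
#' @return Neutral monoisotopic mass `z * mz - z * PROTON_MASS` in Da.
#' @examples
#' mass_from_mz(1050.9996, 2)
#' @export
mass_from_mz <- function(mz, z) {
  if (!is.numeric(z) || any(z < 1) || any(z != round(z))) {
    stop("charge z must be a positive integer")
  }
  if (any(mz <= 0)) stop("mz must be positive")
  z * mz - z * PROTON_MASS
}

#' Theoretical m/z of a protonated species
#'
#' @param M neutral monoisotopic mass in Da.
#' @param z positive integer charge.
#' @return `(M + z * PROTON_MASS) / z` in Th.
#' @examples
#' mz_from_mass(mass_from_mz(1050.9996, 2), 3)
#' @export
mz_from_mass <- function(M, z) {
  if (!is.numeric(z) || any(z < 1) || any(z != round(z))) {
    stop("charge z must be a positive integer")
  }
  if (any(M <= 0)) stop("mass must be positive")
  (M + z * PROTON_MASS) / z
}
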