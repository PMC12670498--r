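#' Synthetic metanodin-like topology
#'
#' A stand-in 20-residue lasso topology for examples and simulations:
#' a 10-residue macrolactam ring opened by asparagine and closed on an
#' aspartate (the noncanonical Asn-1 motif), followed by the tail
#' NIQGDHGLNI, with the loop window on tail residues 15-19. The ring
#' filler residues are synthetic -- the genuine ring sequence (and hence
#' the exact neutral mass) is not modelled.
#'
#' @return A [lasso_topology()].
#' @examples
#' top <- metanodin_like_topology()
#' mz_from_mass(neutral_mass(top$core, "lasso"), 2)
#' @export
metanodin_like_topology <- function() {
  lasso_topology(paste0("NGSAVLHTFD", "NIQGDHGLNI"), ring_size = 10L,
                 loop_window = c(15L, 19L))
}
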