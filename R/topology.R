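#' Lasso peptide topology
#'
#' Describes a mature lasso peptide: the core sequence of length N, the
#' macrolactam ring formed by residues 1..r (the isopeptide bond links
#' the alpha-amine of residue 1 to the side-chain carboxyl of the Asp or
#' Glu at position r), and optionally the loop window -- the inclusive
#' 1-based residue interval of the tail, below the steric lock, within
#' which double cleavages can yield interlocked b/y species.
#'
#' @param core amino-acid string (the mature core peptide, N residues).
#' @param ring_size integer r with `2 <= r < N`; `core` must carry D or E
#'   at position r.
#' @param loop_window optional integer vector `c(lo, hi)` with
#'   `r < lo <= hi <= N`. Required by [enumerate_interlocked()].
#' @return An object of class `lasso_topology`.
#' @examples
#' lasso_topology("NADGG", ring_size = 3, loop_window = c(4, 5))
#' @export
lasso_topology <- function(core, ring_size, loop_window = NULL) {
  aa <- .aa_vec(core)
  n <- length(aa)
  r <- as.integer(ring_size)
  if (is.na(r) || r < 2L || r >= n) {
    stop("ring_size must satisfy 2 <= r < length(core)")
  }
  if (!aa[r] %in% c("D", "E")) {
    stop(sprintf("ring acceptor core[%d] must be D or E, found '%s'", r, aa[r]))
  }
  if (!is.null(loop_window)) {
    loop_window <- as.integer(loop_window)
    if (length(loop_window) != 2L || anyNA(loop_window) ||
        loop_window[1L] > loop_window[2L] ||
        loop_window[1L] <= r || loop_window[2L] > n) {
      stop("loop_window must be c(lo, hi) with ring_size < lo <= hi <= N")
    }
  }
  structure(
    list(core = core, residues = aa, masses = unname(RESIDUE_MASSES[aa]),
         N = n, ring_size = r, acceptor_pos = r, loop_window = loop_window),
    class = "lasso_topology"
  )
}

#' @export
print.lasso_topology <- function(x, ...) {
  cat(sprintf("Lasso topology: %s\n", x$core))
  cat(sprintf("  N = %d, ring = 1..%d (acceptor %s%d), tail = %d..%d\n",
              x$N, x$ring_size, x$residues[x$ring_size], x$ring_size,
              x$ring_size + 1L, x$N))
  if (!is.null(x$loop_window)) {
    cat(sprintf("  loop window: residues %d..%d\n",
                x$loop_window[1L], x$loop_window[2L]))
  }
  cat(sprintf("  neutral monoisotopic mass (lasso): %.5f Da\n",
              neutral_mass(x$core, "lasso")))
  invisible(x)
}

.check_topology <- function(top) {
  if (!inherits(top, "lasso_topology")) {
    stop("expected a 'lasso_topology' object; see lasso_topology()")
  }
  top
}
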