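## Theoretical fragment enumeration for threaded (lasso) peptides.
##
## Water accounting: the lasso neutral mass is the bare residue sum (ring
## closure condensed out one water). The closure deficit is carried on the
## N-terminal (b-side) moiety, so neutral(b_i) = sum(1..i) - water while y
## ions keep the standard +water. This is forced by the complementarity
## identity neutral(b_i) + neutral(y_{N-i}) = M(lasso).

.frag_cols <- c("label", "kind", "i", "j", "opening_site", "z",
                "neutral_mass", "mz")

.new_fragments <- function(df) {
  for (col in .frag_cols) if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[, .frag_cols]
  class(df) <- c("fragment_ions", "data.frame")
  df
}

.check_charges <- function(charges) {
  charges <- as.integer(charges)
  if (length(charges) == 0L || anyNA(charges) || any(charges < 1L)) {
    stop("charges must be a non-empty set of positive integers")
  }
  sort(unique(charges))
}

.at_charges <- function(df, charges) {
  out <- df[rep(seq_len(nrow(df)), each = length(charges)), , drop = FALSE]
  out$z <- rep(charges, times = nrow(df))
  out$mz <- (out$neutral_mass + out$z * PROTON_MASS) / out$z
  rownames(out) <- NULL
  out
}

#' Tail b and y ions of a lasso peptide
#'
#' b ions covering the intact ring plus part of the tail (i = r..N-1) and
#' y ions of the tail (j = 1..N-r), at each requested charge. b ions carry
#' the ring-closure water deficit; y ions are standard.
#'
#' @param top a [lasso_topology()].
#' @param charges positive integer charges; default 1:3.
#' @return A `fragment_ions` data frame.
#' @export
tail_by_ions <- function(top, charges = 1:3) {
  top <- .check_topology(top)
  charges <- .check_charges(charges)
  n <- top$N
  r <- top$ring_size
  pre <- cumsum(top$masses)
  suf <- cumsum(rev(top$masses))
  bi <- r:(n - 1L)
  yj <- 1:(n - r)
  df <- rbind(
    data.frame(label = sprintf("b%d", bi), kind = "b_tail", i = bi, j = NA,
               opening_site = NA, neutral_mass = pre[bi] - WATER_MASS,
               stringsAsFactors = FALSE),
    data.frame(label = sprintf("y%d", yj), kind = "y_tail", i = NA, j = yj,
               opening_site = NA, neutral_mass = suf[yj] + WATER_MASS,
               stringsAsFactors = FALSE)
  )
  .new_fragments(.at_charges(df, charges))
}

#' Linearized forms from macrolactam ring opening
#'
#' HCD cleaves the constrained ring at random backbone amides. Opening
#' the bond between ring residues k and k+1 (k = 1..r-1) linearizes the
#' ring into residue order `[k+1, ..., r, 1, ..., k]`; the isopeptide
#' bond itself is never the opened bond, so a ring of r residues yields
#' exactly r-1 distinct linearized forms.
#'
#' @param top a [lasso_topology()].
#' @return A list with one element per opening site k: `list(site, order,
#'   seq)` where `order` holds original ring indices.
#' @export
enumerate_ring_openings <- function(top) {
  top <- .check_topology(top)
  r <- top$ring_size
  lapply(seq_len(r - 1L), function(k) {
    ord <- c((k + 1L):r, 1L:k)
    list(site = k, order = ord,
         seq = paste(top$residues[ord], collapse = ""))
  })
}

#' Diagnostic b ions of ring-opened linearized forms
#'
#' For every ring opening and every prefix length m (1..r-1) of the
#' linearized residue order, one secondary b ion; plus the intact-ring
#' ion b_r. By default the ring-closure water deficit (-water) is kept on
#' these ions so that the full-length prefix reproduces b_r; set
#' `water_offset = "0"` for the bare acylium-style convention. Duplicate
#' m/z values (rotationally symmetric compositions) are retained, each
#' with its own label.
#'
#' @param top a [lasso_topology()].
#' @param charges positive integer charges.
#' @param water_offset `"-water"` (default) or `"0"`.
#' @return A `fragment_ions` data frame; for a 10-residue ring,
#'   9 rotations x 9 prefixes + 1 ring ion = 82 labels per charge.
#' @export
ring_opened_b_ions <- function(top, charges = 1:3,
                               water_offset = c("-water", "0")) {
  top <- .check_topology(top)
  charges <- .check_charges(charges)
  water_offset <- match.arg(water_offset)
  off <- if (water_offset == "-water") -WATER_MASS else 0
  r <- top$ring_size
  rows <- list()
  for (op in enumerate_ring_openings(top)) {
    pm <- cumsum(top$masses[op$order])
    m <- seq_len(r - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("b%d@o%d", m, op$site), kind = "b_ring_opened",
      i = m, j = NA, opening_site = op$site,
      neutral_mass = pm[m] + off, stringsAsFactors = FALSE)
  }
  ring_sum <- sum(top$masses[seq_len(r)])
  rows[[length(rows) + 1L]] <- data.frame(
    label = sprintf("b%d", r), kind = "b_ring_opened", i = r, j = NA,
    opening_site = NA, neutral_mass = ring_sum - WATER_MASS,
    stringsAsFactors = FALSE)
  .new_fragments(.at_charges(do.call(rbind, rows), charges))
}

#' Interlocked [(b_i)*(y_j)] species
#'
#' When two backbone cleavages both fall inside the loop window (between
#' the ring and the steric lock), the resulting b and y fragments stay
#' noncovalently associated because the tail remains threaded through the
#' ring. A cleavage after residue i (the b_i site) and a cleavage before
#' residue N-j+1 (the y_j site) qualify when both residue indices lie in
#' the window and at least one residue is eliminated between them
#' (i + j <= N - 1). The complex neutral mass is the lasso mass minus the
#' eliminated residues.
#'
#' @param top a [lasso_topology()] with `loop_window` set.
#' @param charges positive integer charges.
#' @return A `fragment_ions` data frame with kind `"interlocked"`.
#' @export
enumerate_interlocked <- function(top, charges = 1:3) {
  top <- .check_topology(top)
  charges <- .check_charges(charges)
  if (is.null(top$loop_window)) {
    stop("loop_window is not set on this topology; construct it with ",
         "lasso_topology(core, ring_size, loop_window = c(lo, hi))")
  }
  n <- top$N
  lo <- top$loop_window[1L]
  hi <- top$loop_window[2L]
  pre <- cumsum(top$masses)
  suf <- cumsum(rev(top$masses))
  rows <- list()
  for (i in lo:min(hi, n - 1L)) {
    js <- (n - hi + 1L):(n - lo + 1L)
    js <- js[js >= 1L & i + js <= n - 1L]
    for (j in js) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("(b%d)*(y%d)", i, j), kind = "interlocked",
        i = i, j = j, opening_site = NA,
        neutral_mass = (pre[i] - WATER_MASS) + (suf[j] + WATER_MASS),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(.new_fragments(.at_charges(
      data.frame(label = character(), kind = character(), i = integer(),
                 j = integer(), opening_site = integer(),
                 neutral_mass = numeric(), stringsAsFactors = FALSE),
      charges)))
  }
  .new_fragments(.at_charges(do.call(rbind, rows), charges))
}

#' Internal (b_x y_j) fragments
#'
#' An internal fragment produced by the b_x cleavage (after residue x)
#' and the y_j cleavage (before residue N-j+1): it spans residues
#' N-j+1 .. x and its neutral mass is the bare residue sum of that span.
#'
#' @param top a [lasso_topology()].
#' @param pairs list of `c(x, j)` pairs, or a two-column matrix.
#' @param charges positive integer charges.
#' @return A `fragment_ions` data frame with kind `"internal_by"`.
#' @export
internal_by_fragments <- function(top, pairs, charges = 1:3) {
  top <- .check_topology(top)
  charges <- .check_charges(charges)
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1L)
  n <- top$N
  pre <- cumsum(top$masses)
  rows <- lapply(pairs, function(p) {
    x <- as.integer(p[[1L]])
    j <- as.integer(p[[2L]])
    a <- n - j + 1L
    if (j < 1L || a > x || x > n - 1L) {
      stop(sprintf("internal fragment pair (x=%d, j=%d) spans no residues ",
                   x, j), "or exceeds the sequence: need N-j+1 <= x <= N-1")
    }
    data.frame(label = sprintf("(b%dy%d)", x, j), kind = "internal_by",
               i = x, j = j, opening_site = NA,
               neutral_mass = pre[x] - pre[a - 1L],
               stringsAsFactors = FALSE)
  })
  .new_fragments(.at_charges(do.call(rbind, rows), charges))
}

#' Full theoretical ion list for a lasso topology
#'
#' Aggregates precursor ions, tail b/y ions, ring-opened diagnostic b
#' ions, interlocked species (when a loop window is set), and the
#' internal fragments complementary to each interlocked species
#' (x = N - j, j' = N - i), sorted by m/z. Deterministic for fixed input.
#'
#' @param top a [lasso_topology()].
#' @param charges positive integer charges; default 1:3.
#' @param water_offset convention for ring-opened b ions, see
#'   [ring_opened_b_ions()].
#' @return A `fragment_ions` data frame sorted by m/z.
#' @export
theoretical_spectrum <- function(top, charges = 1:3,
                                 water_offset = c("-water", "0")) {
  top <- .check_topology(top)
  charges <- .check_charges(charges)
  water_offset <- match.arg(water_offset)
  M <- neutral_mass(top$core, "lasso")
  prec <- .new_fragments(.at_charges(data.frame(
    label = "[M+zH]", kind = "precursor", i = NA, j = NA,
    opening_site = NA, neutral_mass = M, stringsAsFactors = FALSE),
    charges))
  prec$label <- sprintf("[M+%dH]%d+", prec$z, prec$z)
  parts <- list(prec, tail_by_ions(top, charges),
                ring_opened_b_ions(top, charges, water_offset))
  if (!is.null(top$loop_window)) {
    il <- enumerate_interlocked(top, charges)
    parts[[length(parts) + 1L]] <- il
    pairs <- unique(il[, c("i", "j")])
    if (nrow(pairs)) {
      comp <- Map(function(i, j) c(top$N - j, top$N - i), pairs$i, pairs$j)
      keep <- vapply(comp, function(p) p[1L] >= top$N - p[2L] + 1L &&
                       p[1L] <= top$N - 1L, logical(1L))
      if (any(keep)) {
        parts[[length(parts) + 1L]] <-
          internal_by_fragments(top, comp[keep], charges)
      }
    }
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$mz, out$label, out$z), ]
  rownames(out) <- NULL
  .new_fragments(out)
}

#' @export
print.fragment_ions <- function(x, ...) {
  cat(sprintf("%d theoretical ions (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$kind)), table(x$kind)),
                    collapse = ", ")))
  NextMethod()
}

#' Write a fragment table as TSV
#'
#' Columns label, kind, i, j, opening_site, z, neutral_mass, mz with m/z
#' printed to 5 decimals.
#'
#' @param ions a `fragment_ions` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fragment_tsv <- function(ions, path) {
  df <- as.data.frame(ions)
  df$neutral_mass <- sprintf("%.5f", df$neutral_mass)
  df$mz <- sprintf("%.5f", df$mz)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fragment table written by [write_fragment_tsv()]
#'
#' @param path TSV file path.
#' @return A `fragment_ions` data frame.
#' @export
read_fragment_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  .new_fragments(df)
}
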