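# Shared fixtures and independent oracles used across test files.

small_top <- function(window = c(4, 5)) {
  lasso_topology("NADGG", ring_size = 3, loop_window = window)
}

pick <- function(v) v[sample.int(length(v), 1L)]

# Random valid topology; masses drawn over the full canonical alphabet.
random_topology <- function(n = pick(5:12), with_window = TRUE) {
  r <- pick(2:(n - 2L))
  aa <- sample(names(RESIDUE_MASSES), n, replace = TRUE)
  aa[r] <- pick(c("D", "E"))
  lo <- pick((r + 1L):n)
  hi <- pick(lo:n)
  lasso_topology(paste(aa, collapse = ""), r,
                 loop_window = if (with_window) c(lo, hi) else NULL)
}

# Brute-force oracle for interlocked enumeration: exhaustive double loop
# over all (i, j), with masses summed directly from the residue table.
oracle_interlocked <- function(top) {
  aa <- strsplit(top$core, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  lo <- top$loop_window[1L]
  hi <- top$loop_window[2L]
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= lo && i <= hi && (n - j + 1L) >= lo && (n - j + 1L) <= hi &&
          i + j <= n - 1L) {
        neutral <- sum(RESIDUE_MASSES[aa[seq_len(i)]]) +
          sum(RESIDUE_MASSES[aa[(n - j + 1L):n]])
        out[[length(out) + 1L]] <- data.frame(i = i, j = j,
                                              neutral = neutral)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(), neutral = numeric()))
  }
  df <- do.call(rbind, out)
  df[order(df$i, df$j), ]
}

# An MS2 spectrum carrying peaks exactly at the given m/z values.
spectrum_at <- function(mzs, intensity = 1000, nce = 25,
                        precursor_mz = NA_real_, precursor_z = NA_integer_) {
  ms_spectrum("planted", 2L, rt = 4, peaks = cbind(mzs, intensity),
              nce = nce, precursor_mz = precursor_mz,
              precursor_z = precursor_z)
}
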