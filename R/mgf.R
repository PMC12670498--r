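## MGF (Mascot Generic Format) reader/writer for centroided peak lists.
## MS1 scans are stored as MGF blocks without PEPMASS/CHARGE and tagged
## MSLEVEL=1; targeted MS2 scans carry PEPMASS, CHARGE and an NCE key.

.new_spectrum <- function(scan_id, ms_level, rt, peaks, nce = NA_real_,
                          precursor_mz = NA_real_, precursor_z = NA_integer_) {
  if (!is.matrix(peaks)) peaks <- matrix(peaks, ncol = 2L)
  colnames(peaks) <- c("mz", "intensity")
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  if (any(peaks[, "intensity"] < 0)) stop("negative peak intensity")
  structure(list(scan_id = scan_id, ms_level = as.integer(ms_level),
                 rt = rt, nce = nce, precursor_mz = precursor_mz,
                 precursor_z = precursor_z, peaks = peaks),
            class = "ms_spectrum")
}

#' Construct a centroided spectrum
#'
#' @param scan_id scan identifier string.
#' @param ms_level 1 or 2.
#' @param rt retention time in minutes.
#' @param peaks two-column matrix (mz, intensity); sorted by m/z on
#'   construction.
#' @param nce normalized collision energy (MS2), or NA.
#' @param precursor_mz,precursor_z precursor selection (MS2 only).
#' @return An `ms_spectrum` object.
#' @export
ms_spectrum <- function(scan_id, ms_level, rt, peaks, nce = NA_real_,
                        precursor_mz = NA_real_,
                        precursor_z = NA_integer_) {
  .new_spectrum(scan_id, ms_level, rt, peaks, nce, precursor_mz,
                precursor_z)
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("MS%d spectrum '%s': %d peaks, RT %.3f min%s\n", x$ms_level,
              x$scan_id, nrow(x$peaks), x$rt,
              if (!is.na(x$nce)) sprintf(", NCE %g", x$nce) else ""))
  invisible(x)
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [ms_spectrum()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    lines <- c("BEGIN IONS",
               sprintf("TITLE=%s", sp$scan_id),
               sprintf("MSLEVEL=%d", sp$ms_level),
               sprintf("RTINSECONDS=%.4f", sp$rt * 60))
    if (!is.na(sp$precursor_mz)) {
      lines <- c(lines, sprintf("PEPMASS=%.5f", sp$precursor_mz))
    }
    if (!is.na(sp$precursor_z)) {
      lines <- c(lines, sprintf("CHARGE=%d+", sp$precursor_z))
    }
    if (!is.na(sp$nce)) lines <- c(lines, sprintf("NCE=%g", sp$nce))
    pk <- sprintf("%.5f %.4f", sp$peaks[, "mz"], sp$peaks[, "intensity"])
    writeLines(c(lines, pk, "END IONS"), con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path MGF file.
#' @return list of [ms_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^BEGIN IONS", lines[i])) { i <- i + 1L; next }
    hdr <- list(TITLE = sprintf("scan%d", length(spectra) + 1L),
                MSLEVEL = "2")
    pk_mz <- numeric()
    pk_int <- numeric()
    i <- i + 1L
    while (i <= n && !grepl("^END IONS", lines[i])) {
      ln <- trimws(lines[i])
      if (nzchar(ln)) {
        if (grepl("=", ln, fixed = TRUE)) {
          key <- toupper(sub("=.*$", "", ln))
          hdr[[key]] <- sub("^[^=]*=", "", ln)
        } else {
          fields <- strsplit(ln, "\\s+")[[1L]]
          pk_mz <- c(pk_mz, as.numeric(fields[1L]))
          pk_int <- c(pk_int, if (length(fields) > 1L)
            as.numeric(fields[2L]) else 0)
        }
      }
      i <- i + 1L
    }
    i <- i + 1L
    rt <- if (!is.null(hdr$RTINSECONDS)) as.numeric(hdr$RTINSECONDS) / 60
      else NA_real_
    pz <- if (!is.null(hdr$CHARGE))
      as.integer(sub("[+-]$", "", hdr$CHARGE)) else NA_integer_
    pmz <- if (!is.null(hdr$PEPMASS))
      as.numeric(strsplit(hdr$PEPMASS, "\\s+")[[1L]][1L]) else NA_real_
    spectra[[length(spectra) + 1L]] <- .new_spectrum(
      scan_id = hdr$TITLE, ms_level = as.integer(hdr$MSLEVEL), rt = rt,
      peaks = cbind(pk_mz, pk_int),
      nce = if (!is.null(hdr$NCE)) as.numeric(hdr$NCE) else NA_real_,
      precursor_mz = pmz, precursor_z = pz)
  }
  spectra
}
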