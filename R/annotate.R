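## Spectrum annotation: ppm windows, extracted ion chromatograms,
## fragment matching, NCE-merged reports and topology classification.

#' m/z window at a ppm tolerance
#'
#' @param target_mz target m/z in Th.
#' @param tol_ppm tolerance in parts per million.
#' @return `c(lo, hi)` = `target * (1 -/+ tol * 1e-6)`.
#' @export
ppm_window <- function(target_mz, tol_ppm) {
  if (target_mz <= 0 || tol_ppm <= 0) {
    stop("target_mz and tol_ppm must be positive")
  }
  target_mz * c(1 - tol_ppm * 1e-6, 1 + tol_ppm * 1e-6)
}

#' Extracted ion chromatogram
#'
#' Per MS1 scan, the summed intensity of peaks within the ppm window
#' around the target m/z, paired with retention time.
#'
#' @param spectra list of [ms_spectrum()] objects (MS1 scans are used;
#'   others ignored).
#' @param target_mz target m/z in Th.
#' @param tol_ppm tolerance in ppm (default 5).
#' @return An object of class `eic`: data frame with columns rt,
#'   intensity, sorted by rt.
#' @export
extract_eic <- function(spectra, target_mz, tol_ppm = 5) {
  win <- ppm_window(target_mz, tol_ppm)
  ms1 <- Filter(function(sp) sp$ms_level == 1L, spectra)
  if (!length(ms1)) stop("no MS1 spectra in input")
  df <- data.frame(
    rt = vapply(ms1, `[[`, numeric(1L), "rt"),
    intensity = vapply(ms1, function(sp) {
      sel <- sp$peaks[, "mz"] >= win[1L] & sp$peaks[, "mz"] <= win[2L]
      sum(sp$peaks[sel, "intensity"])
    }, numeric(1L)))
  df <- df[order(df$rt), ]
  rownames(df) <- NULL
  attr(df, "target_mz") <- target_mz
  attr(df, "tol_ppm") <- tol_ppm
  class(df) <- c("eic", "data.frame")
  df
}

#' @export
plot.eic <- function(x, ...) {
  plot(x$rt, x$intensity, type = "l", xlab = "retention time (min)",
       ylab = "intensity",
       main = sprintf("EIC m/z %.4f (+/- %g ppm)", attr(x, "target_mz"),
                      attr(x, "tol_ppm")), ...)
  invisible(x)
}

#' Estimate the elution apex of an EIC trace
#'
#' Intensity-weighted centroid of the scans at or above `frac` of the
#' trace maximum (quarter-height region by default), which is robust to
#' scan-to-scan intensity noise compared with the raw argmax.
#'
#' @param eic an [extract_eic()] result.
#' @param frac fraction of the maximum defining the apex region.
#' @return Apex retention time in minutes (NA for an all-zero trace).
#' @export
eic_apex <- function(eic, frac = 0.25) {
  m <- max(eic$intensity)
  if (m <= 0) return(NA_real_)
  sel <- eic$intensity >= frac * m
  sum(eic$rt[sel] * eic$intensity[sel]) / sum(eic$intensity[sel])
}

#' Write an EIC trace as two-column TSV
#'
#' @param eic an [extract_eic()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eic_tsv <- function(eic, path) {
  utils::write.table(as.data.frame(eic), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Match theoretical fragment ions against an MS2 spectrum
#'
#' Each theoretical ion is matched to the nearest peak inside its ppm
#' window; one peak may serve several isobaric labels. No intensity
#' weighting is applied.
#'
#' @param spectrum an MS2 [ms_spectrum()].
#' @param theoretical a `fragment_ions` data frame.
#' @param tol_ppm tolerance in ppm (default 5).
#' @return list with `matches` (data frame: theoretical columns plus
#'   mz_obs, intensity, ppm_error) and `unmatched` (theoretical rows with
#'   no in-window peak).
#' @export
match_fragments <- function(spectrum, theoretical, tol_ppm = 5) {
  if (spectrum$ms_level != 2L) stop("match_fragments expects an MS2 spectrum")
  if (!nrow(theoretical)) stop("theoretical ion list is empty")
  mzs <- spectrum$peaks[, "mz"]
  idx <- integer(nrow(theoretical))
  err <- numeric(nrow(theoretical))
  for (k in seq_len(nrow(theoretical))) {
    t <- theoretical$mz[k]
    win <- t * c(1 - tol_ppm * 1e-6, 1 + tol_ppm * 1e-6)
    sel <- which(mzs >= win[1L] & mzs <= win[2L])
    if (!length(sel)) { idx[k] <- NA_integer_; next }
    best <- sel[which.min(abs(mzs[sel] - t))]
    idx[k] <- best
    err[k] <- (mzs[best] - t) / t * 1e6
  }
  hit <- !is.na(idx)
  matches <- as.data.frame(theoretical)[hit, , drop = FALSE]
  if (any(hit)) {
    matches$mz_obs <- mzs[idx[hit]]
    matches$intensity <- spectrum$peaks[idx[hit], "intensity"]
    matches$ppm_error <- err[hit]
  } else {
    matches$mz_obs <- numeric(0)
    matches$intensity <- numeric(0)
    matches$ppm_error <- numeric(0)
  }
  rownames(matches) <- NULL
  unmatched <- as.data.frame(theoretical)[!hit, , drop = FALSE]
  rownames(unmatched) <- NULL
  list(matches = matches, unmatched = unmatched)
}

#' Annotate targeted MS2 scans against a lasso topology
#'
#' Matches the full theoretical ion list in every MS2 spectrum and
#' merges evidence across collision energies as a union of matches.
#' Spectra whose precursor selection is inconsistent with the topology
#' (outside half the isolation window of any theoretical precursor m/z
#' at the recorded charge) trigger a warning but are still annotated.
#'
#' @param spectra list of [ms_spectrum()] objects (MS2 scans are used).
#' @param top a [lasso_topology()].
#' @param tol_ppm tolerance in ppm (default 5).
#' @param charges fragment charges to enumerate (default 1:3).
#' @param water_offset ring-opened b ion convention, see
#'   [ring_opened_b_ions()].
#' @param isolation_da precursor isolation window width in Da (default 2).
#' @return An object of class `lasso_annotation`: coverage fractions for
#'   the tail b and y series, the merged match table, per-rotation
#'   ring-opened b matches, matched interlocked and internal species.
#' @export
annotate_run <- function(spectra, top, tol_ppm = 5, charges = 1:3,
                         water_offset = "-water", isolation_da = 2) {
  top <- .check_topology(top)
  ms2 <- Filter(function(sp) sp$ms_level == 2L, spectra)
  if (!length(ms2)) stop("no MS2 spectra in input")
  theo <- theoretical_spectrum(top, charges, water_offset)
  theo$uid <- paste0(theo$label, "/", theo$z)
  prec <- theo[theo$kind == "precursor", ]
  hit_uid <- character()
  all_matches <- list()
  for (sp in ms2) {
    if (!is.na(sp$precursor_mz) && !is.na(sp$precursor_z)) {
      pm <- prec$mz[prec$z == sp$precursor_z]
      if (length(pm) && min(abs(pm - sp$precursor_mz)) > isolation_da / 2) {
        warning(sprintf(
          "scan '%s': precursor m/z %.4f (z=%d) inconsistent with topology",
          sp$scan_id, sp$precursor_mz, sp$precursor_z))
      }
    }
    mr <- match_fragments(sp, theo, tol_ppm)
    if (nrow(mr$matches)) {
      mr$matches$scan_id <- sp$scan_id
      mr$matches$nce <- sp$nce
      all_matches[[length(all_matches) + 1L]] <- mr$matches
      hit_uid <- union(hit_uid, mr$matches$uid)
    }
  }
  merged <- theo[theo$uid %in% hit_uid, ]
  n <- top$N
  r <- top$ring_size
  b_idx <- r:(n - 1L)
  y_idx <- 1:(n - r)
  b_hit <- unique(merged$i[merged$kind == "b_tail"])
  y_hit <- unique(merged$j[merged$kind == "y_tail"])
  rot <- merged[merged$kind == "b_ring_opened" & !is.na(merged$opening_site), ]
  rot_tab <- if (nrow(rot)) {
    stats::aggregate(list(n_matched = rot$uid),
                     by = list(opening_site = rot$opening_site),
                     FUN = function(x) length(unique(x)))
  } else {
    data.frame(opening_site = integer(), n_matched = integer())
  }
  il <- unique(merged$label[merged$kind == "interlocked"])
  internal <- unique(merged$label[merged$kind == "internal_by"])
  structure(list(
    tail_b_coverage = length(intersect(b_hit, b_idx)) / length(b_idx),
    tail_y_coverage = length(intersect(y_hit, y_idx)) / length(y_idx),
    matched_b = sort(intersect(b_hit, b_idx)),
    matched_y = sort(intersect(y_hit, y_idx)),
    ring_opened = rot_tab,
    n_ring_opened_labels = length(unique(rot$label)),
    interlocked = sort(il),
    n_interlocked = length(il),
    internal = sort(internal),
    matched = merged,
    matches_by_scan = if (length(all_matches))
      do.call(rbind, all_matches) else NULL,
    n_spectra = length(ms2),
    nces = sort(unique(vapply(ms2, `[[`, numeric(1L), "nce"))),
    tol_ppm = tol_ppm),
    class = "lasso_annotation")
}

#' @export
print.lasso_annotation <- function(x, ...) {
  cat(sprintf("Lasso MS2 annotation (%d spectra, NCE %s, +/-%g ppm)\n",
              x$n_spectra, paste(x$nces, collapse = "/"), x$tol_ppm))
  cat(sprintf("  tail b coverage: %.0f%% (b%s)\n", 100 * x$tail_b_coverage,
              paste(x$matched_b, collapse = ",b")))
  cat(sprintf("  tail y coverage: %.0f%% (y%s)\n", 100 * x$tail_y_coverage,
              paste(x$matched_y, collapse = ",y")))
  cat(sprintf("  ring-opened diagnostic b labels matched: %d\n",
              x$n_ring_opened_labels))
  cat(sprintf("  interlocked species: %d%s\n", x$n_interlocked,
              if (x$n_interlocked) paste0(" [",
                paste(x$interlocked, collapse = ", "), "]") else ""))
  if (length(x$internal)) {
    cat(sprintf("  internal fragments: %s\n",
                paste(x$internal, collapse = ", ")))
  }
  invisible(x)
}

#' Call threaded (lasso) topology from an annotation report
#'
#' The threaded conformation is supported when at least `min_interlocked`
#' interlocked [(b_i)*(y_j)] species were matched -- these only survive
#' when the tail is mechanically trapped in the ring -- together with a
#' tail y coverage of at least `min_y_cov` confirming the sequence.
#'
#' @param report a [annotate_run()] result.
#' @param min_interlocked minimum matched interlocked species (default 1).
#' @param min_y_cov minimum tail y-ion coverage fraction (default 0.5).
#' @return `"threaded_supported"` or `"inconclusive"`.
#' @export
classify_topology <- function(report, min_interlocked = 1L,
                              min_y_cov = 0.5) {
  if (report$n_interlocked >= min_interlocked &&
      report$tail_y_coverage >= min_y_cov) {
    "threaded_supported"
  } else {
    "inconclusive"
  }
}

#' Write an annotation report as JSON + TSV
#'
#' @param report a [annotate_run()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_annotation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  matched <- as.data.frame(report$matched)
  matched$neutral_mass <- sprintf("%.5f", matched$neutral_mass)
  matched$mz <- sprintf("%.5f", matched$mz)
  utils::write.table(matched, file.path(dir, "matched_ions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- list(
    tail_b_coverage = report$tail_b_coverage,
    tail_y_coverage = report$tail_y_coverage,
    matched_b = report$matched_b, matched_y = report$matched_y,
    n_ring_opened_labels = report$n_ring_opened_labels,
    interlocked = report$interlocked, internal = report$internal,
    n_spectra = report$n_spectra, nces = report$nces,
    tol_ppm = report$tol_ppm)
  jsonlite::write_json(payload, file.path(dir, "annotation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
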