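test_that("ppm windows scale with the target m/z", {
  w <- ppm_window(1050.9996, 5)
  expect_equal(diff(w) / 2, 1050.9996 * 5e-6, tolerance = 1e-9)
  expect_equal(ppm_window(100, 10), c(99.999, 100.001))
  expect_true(w[1] < 1050.9996 && 1050.9996 < w[2])
  expect_error(ppm_window(-1, 5), "positive")
})

test_that("MGF files round-trip spectra with metadata", {
  cfg <- synth_config(seed = 71)
  sp <- simulate_ms2(metanodin_like_topology(), cfg)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  back <- read_mgf(path)
  expect_length(back, length(sp))
  for (k in seq_along(sp)) {
    expect_equal(back[[k]]$scan_id, sp[[k]]$scan_id)
    expect_equal(back[[k]]$ms_level, sp[[k]]$ms_level)
    expect_equal(back[[k]]$nce, sp[[k]]$nce)
    expect_equal(back[[k]]$precursor_z, sp[[k]]$precursor_z)
    expect_equal(back[[k]]$peaks[, "mz"], sp[[k]]$peaks[, "mz"],
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
  # MS1 blocks survive too
  run <- simulate_ms1_run(2000, 2, synth_config(seed = 72, rt_range = c(0, 1)))
  write_mgf(run, path)
  back1 <- read_mgf(path)
  expect_true(all(vapply(back1, `[[`, integer(1L), "ms_level") == 1L))
})

test_that("EIC extraction recovers a planted elution profile", {
  M <- 2103.01333
  cfg <- synth_config(seed = 73)
  run <- simulate_ms1_run(M, charges = 2, cfg)
  eic <- extract_eic(run, mz_from_mass(M, 2), tol_ppm = 5)
  expect_lt(abs(eic_apex(eic) - cfg$rt_apex), cfg$rt_step)
  # absent target: all-zero trace
  zero <- extract_eic(run, 900, tol_ppm = 5)
  expect_true(all(zero$intensity == 0))
  expect_true(is.na(eic_apex(zero)))
  # linearity in intensity
  run2 <- lapply(run, function(sp) {
    sp$peaks[, "intensity"] <- 2 * sp$peaks[, "intensity"]
    sp
  })
  eic2 <- extract_eic(run2, mz_from_mass(M, 2), tol_ppm = 5)
  expect_equal(eic2$intensity, 2 * eic$intensity)
})

test_that("fragment matching honours the ppm window and shares peaks", {
  top <- small_top()
  theo <- tail_by_ions(top, charges = 1)
  sp <- spectrum_at(theo$mz)
  mr <- match_fragments(sp, theo, tol_ppm = 5)
  expect_equal(nrow(mr$matches), nrow(theo))
  expect_equal(mr$matches$ppm_error, rep(0, nrow(theo)))
  # a +20 ppm calibration error kills every match at 5 ppm
  sp_shift <- spectrum_at(theo$mz * (1 + 20e-6))
  mr_shift <- match_fragments(sp_shift, theo, tol_ppm = 5)
  expect_equal(nrow(mr_shift$matches), 0L)
  expect_equal(nrow(mr_shift$unmatched), nrow(theo))
  # two isobaric theoreticals 1 ppm apart share one peak
  iso <- theo[c(1L, 1L), ]
  iso$mz[2L] <- iso$mz[1L] * (1 + 1e-6)
  mr_iso <- match_fragments(spectrum_at(iso$mz[1L]), iso, tol_ppm = 5)
  expect_equal(nrow(mr_iso$matches), 2L)
  expect_equal(length(unique(mr_iso$matches$mz_obs)), 1L)
  expect_error(match_fragments(
    ms_spectrum("s", 1L, 1, cbind(100, 1)), theo), "MS2")
})

test_that("annotation reports exactly the planted tail ion subset", {
  top <- metanodin_like_topology()
  tb <- tail_by_ions(top, charges = 1)
  planted <- tb[(tb$kind == "b_tail" & tb$i %in% c(10:13, 15, 16)) |
                  (tb$kind == "y_tail" & tb$j %in% 2:10), ]
  rep <- annotate_run(list(spectrum_at(planted$mz)), top, charges = 1)
  expect_equal(rep$matched_b, c(10:13, 15L, 16L))
  expect_equal(rep$matched_y, 2:10)
  expect_equal(rep$tail_y_coverage, 0.9)
  expect_equal(rep$n_interlocked, 0L)
})

test_that("interlocked evidence is counted and drives the topology call", {
  top <- metanodin_like_topology()
  il <- enumerate_interlocked(top, charges = 2)
  three <- il[il$label %in% c("(b17)*(y2)", "(b15)*(y4)", "(b15)*(y2)"), ]
  tb <- tail_by_ions(top, charges = 1)
  ys <- tb[tb$kind == "y_tail" & tb$j %in% 2:10, ]
  rep <- annotate_run(list(spectrum_at(c(three$mz, ys$mz))), top)
  expect_equal(rep$n_interlocked, 3L)
  expect_setequal(rep$interlocked,
                  c("(b17)*(y2)", "(b15)*(y4)", "(b15)*(y2)"))
  expect_equal(classify_topology(rep), "threaded_supported")
  # raising the interlocked threshold can only withdraw the call
  expect_equal(classify_topology(rep, min_interlocked = 4L), "inconclusive")
  # no interlocked species: inconclusive regardless of coverage
  rep_y <- annotate_run(list(spectrum_at(ys$mz)), top)
  expect_equal(classify_topology(rep_y), "inconclusive")
  # empty spectrum: all coverages zero
  empty <- ms_spectrum("e", 2L, 1, matrix(numeric(), ncol = 2L))
  rep0 <- annotate_run(list(empty), top)
  expect_equal(rep0$tail_b_coverage, 0)
  expect_equal(rep0$tail_y_coverage, 0)
})

test_that("a precursor selection off the topology raises a warning", {
  top <- metanodin_like_topology()
  tb <- tail_by_ions(top, charges = 1)
  sp <- spectrum_at(tb$mz, precursor_mz = 800, precursor_z = 2L)
  expect_warning(annotate_run(list(sp), top), "inconsistent")
})

test_that("decoy-only spectra match below the window-coverage bound", {
  top <- metanodin_like_topology()
  theo <- theoretical_spectrum(top)
  rate <- 0.2   # decoy peaks per Th, dense null
  set.seed(74)
  hits <- 0L
  total <- 0L
  for (k in 1:30) {
    n <- stats::rpois(1L, rate * 2300)
    sp <- ms_spectrum(sprintf("d%d", k), 2L, 1,
                      cbind(stats::runif(n, 200, 2500),
                            stats::rexp(n, 1 / 100)))
    mr <- match_fragments(sp, theo, tol_ppm = 5)
    hits <- hits + nrow(mr$matches)
    total <- total + nrow(theo)
  }
  bound <- rate * 2 * 5e-6 * 2500   # per-ion bound at the scan-range edge
  expect_lt(hits / total, bound)
})

test_that("annotation reports serialize to JSON and TSV", {
  top <- metanodin_like_topology()
  sp <- simulate_ms2(top, synth_config(seed = 75))
  rep <- annotate_run(sp, top)
  dir <- withr::local_tempdir()
  write_annotation_report(rep, dir)
  js <- jsonlite::read_json(file.path(dir, "annotation.json"))
  expect_equal(js$tail_b_coverage, rep$tail_b_coverage)
  expect_equal(length(js$interlocked), rep$n_interlocked)
  tsv <- utils::read.table(file.path(dir, "matched_ions.tsv"), sep = "\t",
                           header = TRUE)
  expect_equal(nrow(tsv), nrow(rep$matched))
})
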