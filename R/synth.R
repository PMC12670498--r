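## Seeded synthetic-data generators: precursors with planted motifs, BGC
## contigs with role-labelled truth annotations, and simulated MS1/MS2
## peak lists with ppm-scale m/z jitter, intensity spread and decoy
## peaks. Everything downstream of the seed is deterministic.

## Most-used E. coli codon per amino acid; fixed for determinism.
.ecoli_codon <- c(
  A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTG")

.rev_translate <- function(protein) {
  paste(.ecoli_codon[strsplit(protein, "", fixed = TRUE)[[1L]]],
        collapse = "")
}

## Residues that can never seed a candidate split: no acceptor (D/E), no
## starter-set member. Used for decoys and for core positions that must
## not create competing candidates.
.inert_aa <- c("V", "L", "I", "P", "F", "W", "Y", "H", "K", "R", "M")

.rand_aa <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Random intergenic DNA free of Shine-Dalgarno-like 4-mers, so that the
## refactoring step deterministically calls for the optimized RBS.
## Occurrences are scrubbed by mutating one base rather than resampled,
## so generation cost is linear in length.
.rand_intergenic <- function(n) {
  s <- .rand_dna(n)
  repeat {
    hit <- regexpr("AGGA|GGAG|GAGG", s)
    if (hit == -1L) return(s)
    at <- hit + 1L
    cur <- substr(s, at, at)
    substr(s, at, at) <- c(A = "C", C = "T", G = "T", T = "C")[[cur]]
  }
}

#' Synthetic-data configuration
#'
#' Defaults mirror the study conditions: a 10-residue macrolactam ring
#' with a 10-residue tail (loop window spanning the tail residues below
#' a terminal steric lock), contigs above the 5 kb mining cutoff,
#' targeted MS2 at NCE 15/25/35/45 over a 200-2500 Th scan range with
#' +/-ppm-scale mass error, and a simulated LC elution peak within a
#' 10-minute gradient.
#'
#' @param seed integer RNG seed; identical seed implies identical output.
#' @param ring_size,tail_len core geometry (residues).
#' @param leader_len leader length (residues).
#' @param starter ring-forming residue at core position 1.
#' @param loop_window loop window, or NULL for
#'   `c(ring_size + 5, ring_size + tail_len - 1)`.
#' @param contig_len synthetic contig length (bp).
#' @param n_decoy_orfs decoy ORFs planted per contig.
#' @param mz_jitter_ppm Gaussian m/z error sigma (ppm).
#' @param decoy_peak_rate decoy peaks per Th of scan range.
#' @param intensity_cv coefficient of variation of planted intensities.
#' @param abundance mean planted peak intensity (arbitrary units).
#' @param rt_apex,rt_sigma simulated elution apex and width (minutes).
#' @param rt_range,rt_step MS1 time grid (minutes).
#' @param scan_range acquisition m/z range (Th).
#' @param nces normalized collision energies simulated.
#' @param charges fragment/precursor charges simulated.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, ring_size = 10L, tail_len = 10L,
                         leader_len = 20L, starter = "N",
                         loop_window = NULL, contig_len = 6000L,
                         n_decoy_orfs = 5L, mz_jitter_ppm = 2,
                         decoy_peak_rate = 0.02, intensity_cv = 0.3,
                         abundance = 1e5, rt_apex = 4, rt_sigma = 0.15,
                         rt_range = c(0, 10), rt_step = 0.05,
                         scan_range = c(200, 2500),
                         nces = c(15, 25, 35, 45), charges = 1:3) {
  if (ring_size < 2L || tail_len < 3L || leader_len < 8L) {
    stop("need ring_size >= 2, tail_len >= 3, leader_len >= 8")
  }
  if (is.null(loop_window)) {
    loop_window <- c(ring_size + 5L, ring_size + tail_len - 1L)
  }
  if (mz_jitter_ppm < 0 || decoy_peak_rate < 0 || intensity_cv < 0) {
    stop("noise parameters must be >= 0")
  }
  structure(list(seed = as.integer(seed), ring_size = as.integer(ring_size),
                 tail_len = as.integer(tail_len),
                 leader_len = as.integer(leader_len), starter = starter,
                 loop_window = as.integer(loop_window),
                 contig_len = as.integer(contig_len),
                 n_decoy_orfs = as.integer(n_decoy_orfs),
                 mz_jitter_ppm = mz_jitter_ppm,
                 decoy_peak_rate = decoy_peak_rate,
                 intensity_cv = intensity_cv, abundance = abundance,
                 rt_apex = rt_apex, rt_sigma = rt_sigma,
                 rt_range = rt_range, rt_step = rt_step,
                 scan_range = scan_range, nces = nces, charges = charges),
            class = "synth_config")
}

## Precursor generation on the current RNG stream.
.gen_precursor <- function(cfg) {
  r <- cfg$ring_size
  tl <- cfg$tail_len
  ll <- cfg$leader_len
  n_core <- r + tl
  total <- ll + n_core
  if (total < 25L || total > 90L) {
    stop("leader_len + ring_size + tail_len must give a 25-90 aa precursor")
  }
  ## Leader: starts with M, Thr planted at -2 relative to the core, no
  ## acceptor residues anywhere but the planted one.
  leader <- strsplit(.rand_aa(ll, .inert_aa), "", fixed = TRUE)[[1L]]
  leader[1L] <- "M"
  leader[ll - 1L] <- "T"
  ## Core: configured starter, inert residues at positions that could
  ## seed a competing split, the D acceptor at r, inert tail.
  core <- strsplit(.rand_aa(n_core, .inert_aa), "", fixed = TRUE)[[1L]]
  core[1L] <- cfg$starter
  core[r] <- "D"
  protein <- paste(c(leader, core), collapse = "")
  core <- paste(core, collapse = "")
  top <- lasso_topology(core, r, loop_window = cfg$loop_window)
  list(protein = protein, core = core, core_start = ll + 1L,
       topology = top,
       truth = list(core_start = ll + 1L, ring_size = r,
                    acceptor_offset = r, starter = cfg$starter,
                    leader_len = ll))
}

#' Generate a random lasso precursor with planted motifs
#'
#' The planted candidate satisfies every condition of
#' [score_precursor()]: Thr at position -2 relative to the core start, a
#' starter-set residue at core position 1, the D acceptor at the ring
#' size, and an inert tail. All other positions are drawn from residues
#' that cannot seed a competing candidate split, so the planted split is
#' the unique candidate by construction.
#'
#' @param cfg a [synth_config()].
#' @return list with `protein`, `core`, `core_start`, `topology` (a
#'   [lasso_topology()]) and `truth` (planted coordinates).
#' @export
random_precursor <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  .gen_precursor(cfg)
}

#' Generate a synthetic BGC contig with truth annotations
#'
#' Plants a reverse-translated A gene (the precursor from
#' [random_precursor()]) together with dummy B/C (Group I) or B1/B2
#' (Group II) genes, random intergenic DNA free of apparent RBS motifs,
#' optionally an inversely oriented peptidase gene, and decoy ORFs, then
#' pads to `contig_len`. An in-frame stop codon is placed immediately
#' upstream of every planted gene so ORF scanning recovers the planted
#' coordinates exactly.
#'
#' @param cfg a [synth_config()].
#' @param group `"group_I"` or `"group_II"`.
#' @param include_peptidase plant an inverted peptidase gene.
#' @return list with `contig` (named character vector of length 1),
#'   `genes` (truth annotation data frame as in [read_role_gff3()]),
#'   `precursor` (the [random_precursor()] value).
#' @export
synth_bgc_contig <- function(cfg = synth_config(), group = "group_I",
                             include_peptidase = TRUE) {
  set.seed(cfg$seed)
  prec <- .gen_precursor(cfg)
  cid <- sprintf("synth_contig_%d", cfg$seed)

  dummy_gene <- function(n_aa) {
    .rev_translate(paste0("M", .rand_aa(n_aa - 1L, .inert_aa)))
  }
  gene_seqs <- list(A = paste0(.rev_translate(prec$protein), "TAA"))
  roles <- switch(group,
    group_I = c("B", "C"),
    group_II = c("B1", "B2", "C"),
    stop("group must be 'group_I' or 'group_II'"))
  for (ro in roles) {
    gene_seqs[[ro]] <- paste0(dummy_gene(sample(120:180, 1L)), "TAA")
  }

  parts <- character()
  genes <- list()
  pos <- 0L
  add_dna <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  add_gene <- function(id, role, seq, strand = "+") {
    p0 <- pos
    if (strand == "+") {
      ## in-frame stop immediately upstream pins the ORF start
      add_dna(paste0("TAA", seq))
      start <- p0 + 4L
      end <- p0 + 3L + nchar(seq)
    } else {
      ## on the reverse strand "upstream" is to the right on the forward
      add_dna(paste0(.revcomp(seq), "TTA"))
      start <- p0 + 1L
      end <- p0 + nchar(seq)
    }
    genes[[length(genes) + 1L]] <<- data.frame(
      seqid = cid, start = start, end = end, strand = strand, role = role,
      id = id, stringsAsFactors = FALSE)
  }

  add_dna(.rand_intergenic(sample(150:300, 1L)))
  add_gene("geneA", "A", gene_seqs$A)
  for (ro in roles) {
    add_dna(.rand_intergenic(sample(40:80, 1L)))
    add_gene(paste0("gene", ro), ro, gene_seqs[[ro]])
  }
  if (include_peptidase) {
    add_dna(.rand_intergenic(sample(40:80, 1L)))
    add_gene("genePep", "peptidase",
             paste0(dummy_gene(sample(100:140, 1L)), "TAA"), strand = "-")
  }
  for (k in seq_len(cfg$n_decoy_orfs)) {
    add_dna(.rand_intergenic(sample(40:120, 1L)))
    strand <- if (k %% 2L == 0L) "-" else "+"
    add_gene(sprintf("decoy%02d", k), "other",
             paste0(dummy_gene(sample(25:45, 1L)), "TAA"), strand = strand)
  }
  pad <- cfg$contig_len - pos
  if (pad < 0L) stop("contig_len too small for the planted parts")
  if (pad > 0L) add_dna(.rand_intergenic(pad))

  contig <- paste(parts, collapse = "")
  names(contig) <- cid
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  list(contig = contig, genes = genes, precursor = prec, group = group)
}

.lognorm_intensity <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.decoy_peaks <- function(rate, scan_range) {
  n <- stats::rpois(1L, rate * diff(scan_range))
  if (n == 0L) return(cbind(mz = numeric(), intensity = numeric()))
  cbind(mz = stats::runif(n, scan_range[1L], scan_range[2L]),
        intensity = stats::rexp(n, rate = 1 / 100))
}

#' Simulate targeted MS2 spectra of a lasso topology
#'
#' One spectrum per collision energy: the full theoretical ion list
#' (restricted to the scan range) with Gaussian m/z jitter of
#' `mz_jitter_ppm` ppm and log-normal intensity spread, plus Poisson
#' decoy peaks uniform in m/z with exponential intensities. The planted
#' ion identities are recorded in the `"truth"` attribute (per spectrum
#' and as the union over energies).
#'
#' @param top a [lasso_topology()].
#' @param cfg a [synth_config()].
#' @return list of MS2 [ms_spectrum()] objects with a `"truth"`
#'   attribute.
#' @export
simulate_ms2 <- function(top, cfg = synth_config()) {
  top <- .check_topology(top)
  set.seed(cfg$seed)
  theo <- theoretical_spectrum(top, cfg$charges)
  theo$uid <- paste0(theo$label, "/", theo$z)
  theo <- theo[theo$mz >= cfg$scan_range[1L] &
                 theo$mz <= cfg$scan_range[2L], ]
  prec_mz <- mz_from_mass(neutral_mass(top$core, "lasso"), 2L)
  spectra <- list()
  truth <- list()
  for (nce in cfg$nces) {
    mz <- theo$mz * (1 + stats::rnorm(nrow(theo), 0,
                                      cfg$mz_jitter_ppm * 1e-6))
    int <- .lognorm_intensity(nrow(theo), cfg$abundance, cfg$intensity_cv)
    peaks <- rbind(cbind(mz = mz, intensity = int),
                   .decoy_peaks(cfg$decoy_peak_rate, cfg$scan_range))
    spectra[[length(spectra) + 1L]] <- .new_spectrum(
      scan_id = sprintf("ms2_nce%g", nce), ms_level = 2L,
      rt = cfg$rt_apex, peaks = peaks, nce = nce,
      precursor_mz = prec_mz, precursor_z = 2L)
    truth[[sprintf("nce%g", nce)]] <- theo$uid
  }
  attr(spectra, "truth") <- c(truth, list(union = unique(unlist(truth))))
  spectra
}

#' Simulate an MS1 run with a planted eluting compound
#'
#' Scans on a regular time grid carry the compound's isotope-free
#' monoisotopic peaks at `mz_from_mass(M, z)` for each charge, with a
#' Gaussian elution profile centred on `rt_apex`, m/z jitter and decoy
#' peaks as in [simulate_ms2()].
#'
#' @param M neutral monoisotopic mass in Da.
#' @param charges charge states of the planted ions.
#' @param cfg a [synth_config()].
#' @return list of MS1 [ms_spectrum()] objects.
#' @export
simulate_ms1_run <- function(M, charges = c(2L, 3L),
                             cfg = synth_config()) {
  if (M <= 0) stop("M must be positive")
  set.seed(cfg$seed)
  times <- seq(cfg$rt_range[1L], cfg$rt_range[2L], by = cfg$rt_step)
  target <- mz_from_mass(M, charges)
  keep <- target >= cfg$scan_range[1L] & target <= cfg$scan_range[2L]
  target <- target[keep]
  spectra <- vector("list", length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    amp <- cfg$abundance *
      exp(-(t - cfg$rt_apex)^2 / (2 * cfg$rt_sigma^2))
    mz <- target * (1 + stats::rnorm(length(target), 0,
                                     cfg$mz_jitter_ppm * 1e-6))
    planted <- cbind(mz = mz,
                     intensity = amp * .lognorm_intensity(
                       length(target), 1, cfg$intensity_cv))
    peaks <- rbind(planted, .decoy_peaks(cfg$decoy_peak_rate,
                                         cfg$scan_range))
    spectra[[k]] <- .new_spectrum(scan_id = sprintf("ms1_%04d", k),
                                  ms_level = 1L, rt = t, peaks = peaks)
  }
  spectra
}
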