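## Precursor-gene mining: contig filtering, the A-gene heuristic built
## around the Thr(-2) motif, and BGC architecture classification.

#' Default mining configuration
#'
#' @param min_contig_len keep contigs strictly longer than this (bp).
#' @param min_orf_aa minimum ORF protein length passed to [find_orfs()].
#' @param starter_set residues accepted at core position 1. The canonical
#'   experimentally observed starters G/C/S/A are extended with N
#'   (ring-forming asparagine) and its nearest match Q.
#' @param canonical_starters subset scoring the starter bonus.
#' @param acceptor_range allowed core offsets of the D/E ring acceptor.
#' @param len_range allowed precursor length (aa).
#' @param min_leader,min_tail minimum leader and tail lengths (aa).
#' @param leader_range leader length interval scoring the leader bonus.
#' @param weights named numeric: thr, starter, offset, leader. The score
#'   is a heuristic weighted sum in `[0, 1]`.
#' @return A list of settings for [score_precursor()] and [mine()].
#' @export
mining_config <- function(min_contig_len = 5000L, min_orf_aa = 25L,
                          starter_set = c("G", "C", "S", "A", "N", "Q"),
                          canonical_starters = c("G", "C", "S", "A"),
                          acceptor_range = 7:10,
                          len_range = c(25L, 90L),
                          min_leader = 8L, min_tail = 3L,
                          leader_range = c(10L, 50L),
                          weights = c(thr = 0.4, starter = 0.3,
                                      offset = 0.2, leader = 0.1)) {
  list(min_contig_len = min_contig_len, min_orf_aa = min_orf_aa,
       starter_set = starter_set, canonical_starters = canonical_starters,
       acceptor_range = acceptor_range, len_range = len_range,
       min_leader = min_leader, min_tail = min_tail,
       leader_range = leader_range, weights = weights)
}

#' Filter contigs by length
#'
#' Keeps contigs strictly longer than `min_len` (lasso BGCs are small, so
#' a low cutoff such as 5 kb recovers clusters that a 40 kb cutoff would
#' discard). Order is preserved.
#'
#' @param contigs named character vector of DNA sequences.
#' @param min_len minimum length in bp (exclusive).
#' @return The filtered named character vector.
#' @export
filter_contigs <- function(contigs, min_len = 5000L) {
  if (min_len < 0) stop("min_len must be >= 0")
  contigs[nchar(contigs) > min_len]
}

#' Score leader/core splits of a putative lasso precursor
#'
#' Enumerates every core start position p compatible with a lasso
#' precursor: total length within `len_range`, leader of at least
#' `min_leader` residues, a starter residue from `starter_set` at p, a
#' D or E ring acceptor at some core offset in `acceptor_range`, and at
#' least `min_tail` residues past the acceptor. Each candidate gets a
#' heuristic score: the conserved Thr two residues upstream of the core
#' (weight 0.4), a canonical starter (0.3), a canonical 7-9 ring size
#' (0.2), and a typical leader length (0.1).
#'
#' @param protein amino-acid string (>= 15 residues).
#' @param config a [mining_config()].
#' @return data frame of candidates sorted by decreasing score: columns
#'   core_start, leader, core, ring_residue, acceptor_offset,
#'   has_thr_minus2, score. Empty when no split qualifies.
#' @export
score_precursor <- function(protein, config = mining_config()) {
  aa <- .aa_vec(protein)
  n <- length(aa)
  if (n < 15L) stop("protein too short to be a lasso precursor (< 15 aa)")
  empty <- data.frame(core_start = integer(), leader = character(),
                      core = character(), ring_residue = character(),
                      acceptor_offset = integer(),
                      has_thr_minus2 = logical(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (n < config$len_range[1L] || n > config$len_range[2L]) return(empty)
  w <- config$weights
  rows <- list()
  for (p in seq.int(config$min_leader + 1L, n)) {
    if (!aa[p] %in% config$starter_set) next
    ds <- config$acceptor_range
    ds <- ds[p + ds - 1L <= n]
    ds <- ds[aa[p + ds - 1L] %in% c("D", "E") &
               (n - p + 1L) - ds >= config$min_tail]
    if (!length(ds)) next
    d <- if (any(ds <= 9L)) min(ds[ds <= 9L]) else min(ds)
    thr <- aa[p - 2L] == "T"
    leader_len <- p - 1L
    score <- w[["thr"]] * thr +
      w[["starter"]] * (aa[p] %in% config$canonical_starters) +
      w[["offset"]] * (d %in% 7:9) +
      w[["leader"]] * (leader_len >= config$leader_range[1L] &&
                         leader_len <= config$leader_range[2L])
    rows[[length(rows) + 1L]] <- data.frame(
      core_start = p,
      leader = substr(protein, 1L, p - 1L),
      core = substr(protein, p, n),
      ring_residue = aa[p], acceptor_offset = d, has_thr_minus2 = thr,
      score = score, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$core_start), ]
  rownames(out) <- NULL
  out
}

#' Classify a cluster's gene architecture
#'
#' Group I is the classical proteobacterial ABC layout (roles A, B, C
#' present, no split B); Group II is the nonproteobacterial layout with
#' split B genes (roles A, B1, B2, C).
#'
#' @param genes data frame with a `role` column, or a character vector of
#'   roles.
#' @return `"group_I"`, `"group_II"` or `"unclassified"`.
#' @export
classify_architecture <- function(genes) {
  roles <- if (is.data.frame(genes)) genes$role else genes
  has <- function(x) all(x %in% roles)
  if (has(c("A", "B", "C")) && !any(c("B1", "B2") %in% roles)) {
    "group_I"
  } else if (has(c("A", "B1", "B2", "C"))) {
    "group_II"
  } else {
    "unclassified"
  }
}

#' Are the core biosynthetic genes colinear?
#'
#' TRUE iff all core genes (roles A, B, B1, B2, C) lie on one strand.
#' Accessory genes (peptidase, D, tailoring, other) are ignored -- an
#' inversely oriented peptidase gene does not break colinearity.
#'
#' @param genes data frame with `role` and `strand` columns.
#' @return logical.
#' @export
check_colinearity <- function(genes) {
  core <- genes[genes$role %in% c("A", "B", "B1", "B2", "C"), ]
  if (nrow(core) < 2L) stop("need at least 2 core genes to assess colinearity")
  length(unique(core$strand)) == 1L
}

#' Mine contigs for lasso precursor candidates
#'
#' End-to-end wrapper: filters contigs by length, scans ORFs on both
#' strands, scores every ORF protein as a putative precursor, and (when
#' gene-role annotations are supplied) classifies each contig's cluster
#' architecture and colinearity.
#'
#' @param contigs named character vector of DNA sequences, or the path of
#'   a FASTA file.
#' @param annotations optional data frame of genes (columns seqid, start,
#'   end, strand, role, id), e.g. from [read_role_gff3()], or NULL.
#' @param config a [mining_config()].
#' @return An object of class `lasso_mine_report`: list with `contigs`
#'   (per-contig summary), `candidates` (candidate table) and `bgc`
#'   (per-contig architecture, when annotated).
#' @export
mine <- function(contigs, annotations = NULL, config = mining_config()) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    contigs <- read_contigs(contigs)
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must be uniquely named")
  }
  kept <- filter_contigs(contigs, config$min_contig_len)
  cand_rows <- list()
  summ_rows <- list()
  for (cid in names(kept)) {
    orfs <- find_orfs(kept[[cid]], min_aa = config$min_orf_aa, id = cid)
    n_cand <- 0L
    for (k in seq_len(nrow(orfs))) {
      if (orfs$aa_len[k] < 15L) next
      sc <- score_precursor(orfs$protein[k], config)
      if (!nrow(sc)) next
      sc$contig <- cid
      sc$orf_start <- orfs$start[k]
      sc$orf_end <- orfs$end[k]
      sc$strand <- orfs$strand[k]
      sc$protein <- orfs$protein[k]
      sc$rank <- seq_len(nrow(sc))
      n_cand <- n_cand + nrow(sc)
      cand_rows[[length(cand_rows) + 1L]] <- sc
    }
    summ_rows[[length(summ_rows) + 1L]] <- data.frame(
      contig = cid, length = nchar(kept[[cid]]), n_orfs = nrow(orfs),
      n_candidates = n_cand, stringsAsFactors = FALSE)
  }
  candidates <- if (length(cand_rows)) {
    df <- do.call(rbind, cand_rows)
    df <- df[, c("contig", "orf_start", "orf_end", "strand", "protein",
                 "core_start", "leader", "core", "ring_residue",
                 "acceptor_offset", "has_thr_minus2", "score", "rank")]
    df <- df[order(df$contig, df$orf_start, df$rank), ]
    rownames(df) <- NULL
    df
  } else {
    data.frame(contig = character(), orf_start = integer(),
               orf_end = integer(), strand = character(),
               protein = character(), core_start = integer(),
               leader = character(), core = character(),
               ring_residue = character(), acceptor_offset = integer(),
               has_thr_minus2 = logical(), score = numeric(),
               rank = integer(), stringsAsFactors = FALSE)
  }
  bgc <- NULL
  if (!is.null(annotations) && nrow(annotations)) {
    bgc_rows <- list()
    for (cid in intersect(names(kept), unique(annotations$seqid))) {
      genes <- annotations[annotations$seqid == cid, ]
      arch <- classify_architecture(genes)
      colin <- if (sum(genes$role %in% c("A", "B", "B1", "B2", "C")) >= 2L) {
        check_colinearity(genes)
      } else {
        NA
      }
      bgc_rows[[length(bgc_rows) + 1L]] <- data.frame(
        contig = cid, architecture = arch, colinear = colin,
        n_genes = nrow(genes), stringsAsFactors = FALSE)
    }
    if (length(bgc_rows)) bgc <- do.call(rbind, bgc_rows)
  }
  structure(list(contigs = do.call(rbind, c(summ_rows, list(NULL))),
                 candidates = candidates, bgc = bgc,
                 config = config),
            class = "lasso_mine_report")
}

#' @export
print.lasso_mine_report <- function(x, ...) {
  nc <- if (is.null(x$contigs)) 0L else nrow(x$contigs)
  cat(sprintf("Lasso mining report: %d contig(s) scanned, %d candidate(s)\n",
              nc, nrow(x$candidates)))
  if (nrow(x$candidates)) {
    top <- x$candidates[x$candidates$rank == 1L, ]
    top <- top[order(-top$score), ]
    show <- utils::head(top[, c("contig", "orf_start", "strand",
                                "core_start", "ring_residue",
                                "acceptor_offset", "has_thr_minus2",
                                "score")], 10L)
    print(show, row.names = FALSE)
  }
  if (!is.null(x$bgc)) {
    cat("Cluster architecture:\n")
    print(x$bgc, row.names = FALSE)
  }
  invisible(x)
}

#' Write a mining report as TSV + JSON
#'
#' Deterministic output: identical input yields byte-identical files.
#'
#' @param report a `lasso_mine_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mine_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cand <- report$candidates
  cand$score <- sprintf("%.3f", cand$score)
  utils::write.table(cand, file.path(dir, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  payload <- list(contigs = report$contigs, candidates = report$candidates)
  if (!is.null(report$bgc)) payload$bgc <- report$bgc
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}
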