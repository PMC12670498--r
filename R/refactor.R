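## In-silico refactoring of a prioritized BGC into an expression insert:
## drop isopeptidase genes, re-orient everything to +, replace intergenic
## regions lacking an apparent native RBS with an optimized RBS spacer.

#' Default refactoring options
#'
#' @param rbs optimized ribosome binding site spacer inserted where no
#'   native RBS is apparent (E. coli optimized, 16 bp).
#' @param rbs_core Shine-Dalgarno consensus searched for in native
#'   intergenic regions.
#' @param min_core_match minimum exact match length to `rbs_core`.
#' @param spacing allowed distance range (bp) between the motif 3' end
#'   and the downstream start codon.
#' @param include_transporter keep a D (ABC transporter) gene.
#' @param include_tailoring keep tailoring/modification genes.
#' @param vector_name expression vector recorded on the plan.
#' @return Options list for [plan_refactor()].
#' @export
refactor_options <- function(rbs = "AGAGGAGAAATTAACC",
                             rbs_core = "AGGAGG", min_core_match = 4L,
                             spacing = c(4L, 14L),
                             include_transporter = FALSE,
                             include_tailoring = TRUE,
                             vector_name = "pET28a") {
  list(rbs = rbs, rbs_core = rbs_core, min_core_match = min_core_match,
       spacing = spacing, include_transporter = include_transporter,
       include_tailoring = include_tailoring, vector_name = vector_name)
}

#' Does an intergenic region lack an apparent native RBS?
#'
#' Scans the intergenic sequence immediately upstream of a gene for a
#' Shine-Dalgarno-like motif: an exact match of at least
#' `min_core_match` consecutive bases of `rbs_core` (AGGAGG) whose 3'
#' end lies `spacing[1]`..`spacing[2]` bp upstream of the downstream
#' start codon. Returns TRUE when no such motif is found (an RBS spacer
#' is then needed). The rule is a configurable stand-in for manual
#' inspection.
#'
#' @param intergenic DNA string (may be empty).
#' @param opts a [refactor_options()].
#' @return logical: TRUE if an optimized RBS should be inserted.
#' @export
needs_rbs <- function(intergenic, opts = refactor_options()) {
  L <- nchar(intergenic)
  if (L == 0L) return(TRUE)
  intergenic <- toupper(intergenic)
  core <- opts$rbs_core
  for (len in nchar(core):opts$min_core_match) {
    for (off in 0:(nchar(core) - len)) {
      pat <- substr(core, off + 1L, off + len)
      hits <- gregexpr(pat, intergenic, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      ends <- hits + len - 1L
      gap <- L - ends  # bases between motif 3' end and the start codon
      if (any(gap >= opts$spacing[1L] & gap <= opts$spacing[2L])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

.oriented_bgc <- function(contig, genes) {
  core <- genes[genes$role %in% c("A", "B", "B1", "B2", "C"), ]
  if (!nrow(core)) stop("no core biosynthetic genes in input")
  strands <- unique(core$strand)
  if (length(strands) > 1L) {
    stop("core genes are not colinear; refactoring requires one orientation")
  }
  if (strands == "-") {
    L <- nchar(contig)
    contig <- .revcomp(contig)
    new_start <- L - genes$end + 1L
    genes$end <- L - genes$start + 1L
    genes$start <- new_start
    genes$strand <- ifelse(genes$strand == "-", "+", "-")
  }
  genes <- genes[order(genes$start), ]
  list(contig = contig, genes = genes)
}

#' Plan a refactored expression insert
#'
#' Selects the genes to amplify for the given architecture (Group I:
#' A, B, C, optionally D and tailoring genes; Group II: A, B1, B2, C and
#' tailoring genes), always excludes peptidase genes (lasso isopeptidases
#' can cleave the macrolactam ring and linearize the product), re-orients
#' the cluster to the + strand, and inserts the optimized RBS spacer
#' before every internal gene whose native upstream intergenic region
#' shows no apparent RBS.
#'
#' @param contig DNA string carrying the cluster.
#' @param genes data frame of cluster genes: columns id, start, end,
#'   strand, role.
#' @param group `"group_I"`, `"group_II"` or NULL to auto-classify.
#' @param opts a [refactor_options()].
#' @return An object of class `construct_plan`: ordered `parts` (each
#'   `list(kind, id, role, seq)`), `excluded` (data frame with reasons)
#'   and `vector_name`.
#' @export
plan_refactor <- function(contig, genes, group = NULL,
                          opts = refactor_options()) {
  if (is.null(group)) group <- classify_architecture(genes)
  required <- switch(group,
    group_I = c("A", "B", "C"),
    group_II = c("A", "B1", "B2", "C"),
    stop("cluster is unclassified; cannot plan a refactored construct"))
  missing_roles <- setdiff(required, genes$role)
  if (length(missing_roles)) {
    stop(sprintf("missing required gene role(s): %s",
                 paste(missing_roles, collapse = ", ")))
  }
  ob <- .oriented_bgc(toupper(contig), genes)
  contig <- ob$contig
  genes <- ob$genes

  keep_roles <- required
  if (opts$include_transporter) keep_roles <- c(keep_roles, "D")
  if (opts$include_tailoring) keep_roles <- c(keep_roles, "tailoring")
  reason <- function(role) {
    if (role == "peptidase") "isopeptidase can cleave the macrolactam ring"
    else "role not selected for this architecture"
  }
  excl <- genes[!genes$role %in% keep_roles, ]
  excluded <- if (nrow(excl)) {
    data.frame(id = excl$id, role = excl$role,
               reason = vapply(excl$role, reason, character(1L)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(), role = character(), reason = character(),
               stringsAsFactors = FALSE)
  }

  kept <- genes[genes$role %in% keep_roles, ]
  parts <- list()
  for (k in seq_len(nrow(kept))) {
    g <- kept[k, ]
    gseq <- substr(contig, g$start, g$end)
    if (g$strand == "-") gseq <- .revcomp(gseq)
    if (k > 1L) {
      prev <- kept[k - 1L, ]
      inter <- if (g$start > prev$end + 1L) {
        substr(contig, prev$end + 1L, g$start - 1L)
      } else {
        ""
      }
      if (needs_rbs(inter, opts)) {
        parts[[length(parts) + 1L]] <- list(kind = "rbs_spacer",
                                            id = sprintf("RBS_%d", k - 1L),
                                            role = "rbs", seq = opts$rbs)
      }
    }
    parts[[length(parts) + 1L]] <- list(kind = "gene", id = g$id,
                                        role = g$role, seq = gseq)
  }
  structure(list(parts = parts, excluded = excluded,
                 vector_name = opts$vector_name, group = group,
                 rbs = opts$rbs),
            class = "construct_plan")
}

#' @export
print.construct_plan <- function(x, ...) {
  lab <- vapply(x$parts, function(p) {
    if (p$kind == "gene") sprintf("%s(%s)", p$id, p$role) else "RBS"
  }, character(1L))
  cat(sprintf("Construct plan (%s, vector %s):\n  %s\n", x$group,
              x$vector_name, paste(lab, collapse = " - ")))
  if (nrow(x$excluded)) {
    cat("Excluded:\n")
    print(x$excluded, row.names = FALSE)
  }
  invisible(x)
}

#' Assemble the insert sequence and junction overlaps
#'
#' Concatenates the planned parts into the final insert, records each
#' part's coordinates as features, and reports per junction the terminal
#' `overlap_len` bases on each side (the homology arms a Gibson-style
#' assembly primer would carry). Gene parts containing an in-frame
#' internal stop codon trigger a warning, not a failure.
#'
#' @param plan a [plan_refactor()] result.
#' @param overlap_len overlap length in bp, 15..40.
#' @return An object of class `construct_insert`: `insert_seq`,
#'   `features` (data frame), `junctions` (data frame).
#' @export
build_insert <- function(plan, overlap_len = 20L) {
  if (overlap_len < 15L || overlap_len > 40L) {
    stop("overlap_len must be within [15, 40] bp")
  }
  seqs <- vapply(plan$parts, `[[`, character(1L), "seq")
  ends <- cumsum(nchar(seqs))
  starts <- ends - nchar(seqs) + 1L
  features <- data.frame(
    id = vapply(plan$parts, `[[`, character(1L), "id"),
    kind = vapply(plan$parts, `[[`, character(1L), "kind"),
    role = vapply(plan$parts, `[[`, character(1L), "role"),
    start = starts, end = ends, stringsAsFactors = FALSE)
  insert <- paste(seqs, collapse = "")
  for (k in seq_along(plan$parts)) {
    p <- plan$parts[[k]]
    if (p$kind != "gene") next
    ncod <- nchar(p$seq) %/% 3L
    if (ncod < 2L) next
    codons <- substring(p$seq, 3L * (seq_len(ncod) - 1L) + 1L,
                        3L * seq_len(ncod))
    if (any(codons[-ncod] %in% .stops)) {
      warning(sprintf("gene part '%s' contains an internal in-frame stop",
                      p$id))
    }
  }
  junctions <- if (length(seqs) > 1L) {
    data.frame(
      left = features$id[-nrow(features)],
      right = features$id[-1L],
      left_overlap = vapply(seq_len(length(seqs) - 1L), function(k) {
        s <- seqs[k]
        substr(s, max(1L, nchar(s) - overlap_len + 1L), nchar(s))
      }, character(1L)),
      right_overlap = vapply(seq_len(length(seqs) - 1L) + 1L, function(k) {
        substr(seqs[k], 1L, min(overlap_len, nchar(seqs[k])))
      }, character(1L)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(left = character(), right = character(),
               left_overlap = character(), right_overlap = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(insert_seq = insert, features = features,
                 junctions = junctions, vector_name = plan$vector_name),
            class = "construct_insert")
}

#' @export
print.construct_insert <- function(x, ...) {
  cat(sprintf("Refactored insert: %d bp, %d part(s), for vector %s\n",
              nchar(x$insert_seq), nrow(x$features), x$vector_name))
  print(x$features, row.names = FALSE)
  invisible(x)
}

#' Write the junction-overlap report as TSV
#'
#' @param insert a [build_insert()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junction_tsv <- function(insert, path) {
  utils::write.table(insert$junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
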