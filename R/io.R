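## Standard-format I/O: FASTA via Biostrings, GFF3 via rtracklayer.

#' Read contigs from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of upper-cased DNA sequences.
#' @export
read_contigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write contigs to a FASTA file
#'
#' @param contigs named character vector of DNA sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), path)
  invisible(path)
}

#' Read gene annotations with roles from GFF3
#'
#' Expects `role=` (and optionally `ID=`) attributes on gene features, as
#' written by [write_role_gff3()].
#'
#' @param path GFF3 file.
#' @return data frame with columns seqid, start, end, strand, role, id.
#' @export
read_role_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ids <- if (!is.null(md$ID)) as.character(md$ID) else
    sprintf("gene%02d", seq_along(gr))
  roles <- if (!is.null(md$role)) as.character(md$role) else
    rep("other", length(gr))
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             role = roles, id = ids, stringsAsFactors = FALSE)
}

#' Write gene annotations with roles to GFF3
#'
#' @param genes data frame with columns seqid, start, end, strand, role,
#'   id.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_role_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seqid,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$id
  S4Vectors::mcols(gr)$role <- genes$role
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
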