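## Six-frame ORF scanning with bacterial start codons (genetic code 11).

.iupac <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V")
.starts <- c("ATG", "GTG", "TTG")
.stops <- c("TAA", "TAG", "TGA")

.genetic_code_11 <- function() Biostrings::getGeneticCode("11")

.check_dna <- function(seq) {
  seq <- toupper(seq)
  aa <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!aa %in% .iupac)
  if (length(bad)) {
    stop(sprintf("non-DNA character '%s' at position %d", aa[bad[1L]],
                 bad[1L]))
  }
  chartr("U", "T", seq)
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.translate_codons <- function(codons) {
  code <- .genetic_code_11()
  aa <- code[codons]
  aa[is.na(aa)] <- ""   # ambiguity codes: skip the codon, do not fail
  paste(aa, collapse = "")
}

## ORFs in one frame of one oriented strand; returns offsets in codon units.
.frame_orfs <- function(codons, min_aa) {
  is_stop <- codons %in% .stops
  is_start <- codons %in% .starts
  out <- list()
  seg_begin <- 1L
  for (s in which(is_stop)) {
    starts_in_seg <- which(is_start[seg_begin:(s - 1L)])
    if (s > seg_begin && length(starts_in_seg)) {
      st <- seg_begin + starts_in_seg[1L] - 1L
      if (s - st >= min_aa) {
        out[[length(out) + 1L]] <- c(start = st, stop = s)
      }
    }
    seg_begin <- s + 1L
  }
  out
}

#' Find open reading frames on both strands
#'
#' Scans all six frames for stop-to-stop segments containing an ATG, GTG
#' or TTG start (bacterial genetic code 11), reporting the ORF from the
#' first start codon to the stop. Coordinates are 1-based inclusive on
#' the forward strand and include the stop codon; the translated protein
#' excludes the stop and begins with M regardless of the start codon.
#' Codons containing ambiguity codes are skipped in translation.
#'
#' @param seq DNA string (IUPAC letters; non-DNA characters are an error).
#' @param min_aa minimum protein length in residues (>= 10).
#' @param id contig id recorded in the output.
#' @return data frame with columns id, start, end, strand, aa_len, protein.
#' @export
find_orfs <- function(seq, min_aa = 25L, id = "contig") {
  if (min_aa < 10L) stop("min_aa must be >= 10")
  seq <- .check_dna(seq)
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else .revcomp(seq)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3L
      if (ncod < min_aa + 1L) next
      codons <- substring(s, frame + 3L * (seq_len(ncod) - 1L) + 1L,
                          frame + 3L * seq_len(ncod))
      for (orf in .frame_orfs(codons, min_aa)) {
        b1 <- frame + 3L * (orf[["start"]] - 1L) + 1L   # oriented coords
        b2 <- frame + 3L * orf[["stop"]]
        if (strand == "+") {
          fs <- b1; fe <- b2
        } else {
          fs <- L - b2 + 1L; fe <- L - b1 + 1L
        }
        prot <- .translate_codons(codons[orf[["start"]]:(orf[["stop"]] - 1L)])
        substr(prot, 1L, 1L) <- "M"
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, start = fs, end = fe, strand = strand,
          aa_len = nchar(prot), protein = prot, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(), start = integer(), end = integer(),
                      strand = character(), aa_len = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}
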