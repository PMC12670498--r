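## Minimal GenBank flat-file writer/parser for annotated inserts. Only
## the subset this package emits is supported: LOCUS, FEATURES with
## gene/misc_feature entries carrying /label, /part_kind and /role
## qualifiers, and ORIGIN.

#' Write an annotated insert as a GenBank record
#'
#' @param insert a [build_insert()] result.
#' @param path output file.
#' @param name LOCUS name.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(insert, path, name = "refactored_insert") {
  seq <- tolower(insert$insert_seq)
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     linear   SYN",
                     name, nchar(seq)),
             sprintf("DEFINITION  refactored expression insert for %s.",
                     insert$vector_name),
             "FEATURES             Location/Qualifiers")
  for (k in seq_len(nrow(insert$features))) {
    f <- insert$features[k, ]
    type <- if (f$kind == "gene") "gene" else "misc_feature"
    lines <- c(lines,
               sprintf("     %-15s %d..%d", type, f$start, f$end),
               sprintf("                     /label=\"%s\"", f$id),
               sprintf("                     /part_kind=\"%s\"", f$kind),
               sprintf("                     /role=\"%s\"", f$role))
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1L, nchar(seq), by = 60L)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                             nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank record written by [write_genbank()]
#'
#' @param path GenBank file.
#' @return list with `name`, `length`, `features` (data frame id, kind,
#'   role, start, end) and `seq` (upper-case DNA string).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- strsplit(trimws(sub("^LOCUS", "", lines[1L])), "\\s+")[[1L]]
  name <- locus[1L]
  feat_rows <- list()
  cur <- NULL
  in_origin <- FALSE
  seq_chunks <- character()
  flush <- function(cur, feat_rows) {
    if (!is.null(cur)) feat_rows[[length(feat_rows) + 1L]] <- cur
    feat_rows
  }
  for (ln in lines[-1L]) {
    if (grepl("^ORIGIN", ln)) {
      feat_rows <- flush(cur, feat_rows); cur <- NULL
      in_origin <- TRUE
      next
    }
    if (in_origin) {
      if (grepl("^//", ln)) break
      seq_chunks <- c(seq_chunks, gsub("[^acgtnACGTN]", "", ln))
      next
    }
    m <- regmatches(ln, regexec("^     (\\S+)\\s+(\\d+)\\.\\.(\\d+)", ln))[[1L]]
    if (length(m)) {
      feat_rows <- flush(cur, feat_rows)
      cur <- data.frame(id = NA_character_, kind = NA_character_,
                        role = NA_character_,
                        start = as.integer(m[3L]), end = as.integer(m[4L]),
                        stringsAsFactors = FALSE)
      next
    }
    q <- regmatches(ln, regexec("^\\s+/(\\w+)=\"([^\"]*)\"", ln))[[1L]]
    if (length(q) && !is.null(cur)) {
      key <- q[2L]
      if (key == "label") cur$id <- q[3L]
      if (key == "part_kind") cur$kind <- q[3L]
      if (key == "role") cur$role <- q[3L]
    }
  }
  features <- if (length(feat_rows)) do.call(rbind, feat_rows) else
    data.frame(id = character(), kind = character(), role = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  rownames(features) <- NULL
  list(name = name,
       length = nchar(paste(seq_chunks, collapse = "")),
       features = features,
       seq = toupper(paste(seq_chunks, collapse = "")))
}
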