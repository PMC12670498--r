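test_that("native RBS detection applies the motif/spacing rule", {
  # AGGAGG with its 3' end 8 bp upstream of the start codon: apparent RBS
  expect_false(needs_rbs(paste0("CCCCC", "AGGAGG", strrep("C", 8))))
  # motif flush against the start codon: even the shortest core match
  # ends < 4 bp upstream, so no RBS is apparent
  expect_true(needs_rbs(paste0("CCCCC", "AGGAGG")))
  # motif too far upstream
  expect_true(needs_rbs(paste0("AGGAGG", strrep("C", 20))))
  # a 4-base core match suffices
  expect_false(needs_rbs(paste0("CCCCC", "GGAG", strrep("C", 6))))
  expect_true(needs_rbs(strrep("C", 30)))
  expect_true(needs_rbs(""))
})

test_that("a Group I cluster without native RBS gets the optimized spacer", {
  bgc <- synth_bgc_contig(synth_config(seed = 51))
  plan <- plan_refactor(bgc$contig[[1L]], bgc$genes)
  kinds <- vapply(plan$parts, `[[`, character(1L), "kind")
  roles <- vapply(plan$parts, `[[`, character(1L), "role")
  expect_equal(roles[kinds == "gene"], c("A", "B", "C"))
  expect_equal(kinds, c("gene", "rbs_spacer", "gene", "rbs_spacer", "gene"))
  for (p in plan$parts) {
    if (p$kind == "rbs_spacer") expect_equal(p$seq, "AGAGGAGAAATTAACC")
  }
  expect_true("peptidase" %in% plan$excluded$role)
  expect_match(plan$excluded$reason[plan$excluded$role == "peptidase"],
               "macrolactam")
})

test_that("transporter genes are kept only on request and roles checked", {
  bgc <- synth_bgc_contig(synth_config(seed = 52))
  genes <- rbind(bgc$genes, data.frame(
    seqid = bgc$genes$seqid[1L], start = 5500L, end = 5800L, strand = "+",
    role = "D", id = "geneD"))
  plan <- plan_refactor(bgc$contig[[1L]], genes,
                        opts = refactor_options(include_transporter = TRUE))
  expect_true("D" %in% vapply(plan$parts, `[[`, character(1L), "role"))
  plan2 <- plan_refactor(bgc$contig[[1L]], genes)
  expect_false("D" %in% vapply(plan2$parts, `[[`, character(1L), "role"))
  # a missing required role is named in the error
  noC <- genes[genes$role != "C", ]
  expect_error(plan_refactor(bgc$contig[[1L]], noC, group = "group_I"),
               "missing required gene role\\(s\\): C")
})

test_that("insert length equals gene lengths plus 16 bp per spacer", {
  for (s in c(53, 54)) {
    bgc <- synth_bgc_contig(synth_config(seed = s))
    plan <- plan_refactor(bgc$contig[[1L]], bgc$genes)
    ins <- build_insert(plan)
    gene_len <- sum(vapply(plan$parts, function(p)
      if (p$kind == "gene") nchar(p$seq) else 0L, integer(1L)))
    n_spacer <- sum(vapply(plan$parts, function(p)
      p$kind == "rbs_spacer", logical(1L)))
    expect_equal(nchar(ins$insert_seq), gene_len + 16L * n_spacer)
    # exactly one RBS copy per junction that needed one
    expect_equal(lengths(regmatches(
      ins$insert_seq, gregexpr("AGAGGAGAAATTAACC", ins$insert_seq))),
      n_spacer)
  }
  expect_error(build_insert(plan_refactor(bgc$contig[[1L]], bgc$genes),
                            overlap_len = 10), "15")
})

test_that("junction overlaps mirror the flanking part termini", {
  bgc <- synth_bgc_contig(synth_config(seed = 55))
  ins <- build_insert(plan_refactor(bgc$contig[[1L]], bgc$genes),
                      overlap_len = 20)
  expect_equal(nrow(ins$junctions), nrow(ins$features) - 1L)
  part_seq <- function(k) substr(ins$insert_seq, ins$features$start[k],
                                 ins$features$end[k])
  for (k in seq_len(nrow(ins$junctions))) {
    left <- part_seq(k)
    right <- part_seq(k + 1L)
    # overlaps are truncated at the part boundary (the 16 bp RBS spacer)
    expect_equal(ins$junctions$left_overlap[k],
                 substr(left, max(1L, nchar(left) - 19L), nchar(left)))
    expect_equal(ins$junctions$right_overlap[k],
                 substr(right, 1L, min(20L, nchar(right))))
  }
})

test_that("describing the cluster from the opposite strand changes nothing", {
  bgc <- synth_bgc_contig(synth_config(seed = 56))
  ins1 <- build_insert(plan_refactor(bgc$contig[[1L]], bgc$genes))
  L <- nchar(bgc$contig[[1L]])
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(bgc$contig[[1L]])))
  flipped <- bgc$genes
  flipped$start <- L - bgc$genes$end + 1L
  flipped$end <- L - bgc$genes$start + 1L
  flipped$strand <- ifelse(bgc$genes$strand == "+", "-", "+")
  ins2 <- build_insert(plan_refactor(rc, flipped))
  expect_identical(ins1$insert_seq, ins2$insert_seq)
})

test_that("the annotated GenBank record round-trips the plan", {
  bgc <- synth_bgc_contig(synth_config(seed = 57))
  ins <- build_insert(plan_refactor(bgc$contig[[1L]], bgc$genes))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(ins, path)
  back <- read_genbank(path)
  expect_equal(back$seq, ins$insert_seq)
  expect_equal(back$features$id, ins$features$id)
  expect_equal(back$features$kind, ins$features$kind)
  expect_equal(back$features$start, ins$features$start)
  expect_equal(back$features$end, ins$features$end)
})

test_that("no randomized plan ever retains a peptidase gene", {
  for (s in 61:70) {
    grp <- if (s %% 2L) "group_I" else "group_II"
    bgc <- synth_bgc_contig(synth_config(seed = s), group = grp)
    plan <- plan_refactor(bgc$contig[[1L]], bgc$genes)
    expect_false("peptidase" %in%
                   vapply(plan$parts, `[[`, character(1L), "role"))
    if (grp == "group_II") {
      expect_equal(
        vapply(plan$parts, `[[`, character(1L), "role")[
          vapply(plan$parts, `[[`, character(1L), "kind") == "gene"],
        c("A", "B1", "B2", "C"))
    }
  }
})

test_that("an internal in-frame stop triggers a warning, not a failure", {
  genes <- data.frame(seqid = "c", start = c(4L, 128L, 253L),
                      end = c(126L, 250L, 375L), strand = "+",
                      role = c("A", "B", "C"),
                      id = c("gA", "gB", "gC"), stringsAsFactors = FALSE)
  prot <- paste0("M", strrep("K", 39))
  gene_ok <- paste0(lassomine:::.rev_translate(prot), "TAA")
  broken <- gene_ok
  substr(broken, 31, 33) <- "TGA"
  contig <- paste0("TAA", broken, "C", gene_ok, "CC", gene_ok, "CCC")
  plan <- plan_refactor(contig, genes)
  expect_warning(build_insert(plan), "internal in-frame stop")
})
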