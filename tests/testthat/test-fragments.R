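test_that("topology construction validates ring geometry", {
  expect_s3_class(lasso_topology("NADGG", 3), "lasso_topology")
  expect_error(lasso_topology("NADGG", 1), "ring_size")
  expect_error(lasso_topology("NADGG", 5), "ring_size")
  expect_error(lasso_topology("NAGGG", 3), "must be D or E")
  expect_error(lasso_topology("NADGG", 3, c(3, 5)), "loop_window")
  expect_error(lasso_topology("NADGG", 3, c(4, 6)), "loop_window")
})

test_that("tail b and y ions carry the lasso water accounting", {
  tb <- tail_by_ions(small_top(), charges = 1)
  b3 <- tb[tb$label == "b3", ]
  y2 <- tb[tb$label == "y2", ]
  expect_equal(b3$mz, 300.10698 - 18.0105646 + 1.00727646, tolerance = 1e-8)
  expect_equal(y2$mz, 114.04292 + 18.0105646 + 1.00727646, tolerance = 1e-8)
  expect_error(tail_by_ions(small_top(), charges = integer()), "non-empty")
})

test_that("b/y complementarity recovers the intact lasso mass", {
  set.seed(101)
  for (rep in 1:25) {
    top <- random_topology()
    M <- neutral_mass(top$core, "lasso")
    tb <- tail_by_ions(top, charges = 1)
    for (i in top$ring_size:(top$N - 1L)) {
      nb <- tb$neutral_mass[tb$label == sprintf("b%d", i)]
      ny <- tb$neutral_mass[tb$label == sprintf("y%d", top$N - i)]
      expect_equal(nb + ny, M, tolerance = 1e-9)
    }
  }
})

test_that("b-ion m/z increases strictly with index at fixed charge", {
  set.seed(102)
  for (rep in 1:10) {
    top <- random_topology()
    tb <- tail_by_ions(top, charges = 1:3)
    for (z in 1:3) {
      b <- tb[tb$kind == "b_tail" & tb$z == z, ]
      b <- b[order(b$i), ]
      expect_true(all(diff(b$mz) > 0))
    }
  }
})

test_that("ring opening yields r-1 rotations excluding the isopeptide bond", {
  for (r in 2:12) {
    aa <- c(rep("A", r - 1L), "D", "G", "G", "G")
    top <- lasso_topology(paste(aa, collapse = ""), r)
    expect_length(enumerate_ring_openings(top), r - 1L)
  }
  rot <- enumerate_ring_openings(small_top())
  expect_equal(vapply(rot, `[[`, character(1L), "seq"), c("ADN", "DNA"))
  # r = 2: one backbone bond available
  expect_length(enumerate_ring_openings(lasso_topology("GDGGG", 2)), 1L)
})

test_that("ring-opened secondary b ions follow the configured convention", {
  rb <- ring_opened_b_ions(small_top(), charges = 1)
  m1 <- rb[rb$label == "b1@o1", ]  # rotation [A,D,N], prefix A
  expect_equal(m1$mz, 71.03711 - 18.0105646 + 1.00727646, tolerance = 1e-8)
  # zero offset convention shifts every secondary ion up by one water
  rb0 <- ring_opened_b_ions(small_top(), charges = 1, water_offset = "0")
  sec <- rb$opening_site %in% 1:2
  expect_equal(rb0$neutral_mass[sec] - rb$neutral_mass[sec],
               rep(18.0105646, sum(sec)))
  # intact ring ion is unaffected by the switch
  expect_equal(rb0$neutral_mass[rb0$label == "b3"],
               rb$neutral_mass[rb$label == "b3"])
})

test_that("a 10-residue ring yields 82 diagnostic labels per charge", {
  rb <- ring_opened_b_ions(metanodin_like_topology(), charges = 1)
  expect_equal(nrow(rb), 9 * 9 + 1)
  # full-length prefixes differ across rotations for an asymmetric ring
  full <- rb[!is.na(rb$opening_site) & rb$i == 9, ]
  expect_equal(length(unique(round(full$neutral_mass, 6))), 9L)
})

test_that("interlocked enumeration matches the brute-force oracle", {
  set.seed(103)
  for (rep in 1:40) {
    top <- random_topology(n = pick(5:12))
    got <- enumerate_interlocked(top, charges = 1)
    want <- oracle_interlocked(top)
    got <- got[order(got$i, got$j), ]
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$i, want$i)
      expect_equal(got$j, want$j)
      expect_equal(got$neutral_mass, want$neutral, tolerance = 1e-9)
    }
  }
})

test_that("interlocked species conserve mass and stay below the precursor", {
  top <- metanodin_like_topology()
  il <- enumerate_interlocked(top, charges = 2)
  expect_setequal(
    intersect(il$label, c("(b17)*(y2)", "(b15)*(y4)", "(b15)*(y2)")),
    c("(b17)*(y2)", "(b15)*(y4)", "(b15)*(y2)"))
  M <- neutral_mass(top$core, "lasso")
  aa <- strsplit(top$core, "", fixed = TRUE)[[1L]]
  for (k in seq_len(nrow(il))) {
    eliminated <- sum(RESIDUE_MASSES[aa[(il$i[k] + 1L):(top$N - il$j[k])]])
    expect_equal(il$neutral_mass[k], M - eliminated, tolerance = 1e-9)
    expect_lt(il$neutral_mass[k], M)
  }
  expect_error(enumerate_interlocked(lasso_topology("NADGG", 3), 1),
               "loop_window")
})

test_that("internal fragments span the residues between the two cleavages", {
  top <- small_top()
  int <- internal_by_fragments(top, list(c(4, 2)), charges = 1)
  expect_equal(int$neutral_mass, 57.02146)  # single G span
  expect_equal(int$mz, 57.02146 + 1.00727646, tolerance = 1e-8)
  # (b18 y5) on an N=20 topology spans residues 16..18
  mt <- metanodin_like_topology()
  int2 <- internal_by_fragments(mt, list(c(18, 5)), charges = 1)
  aa <- strsplit(mt$core, "", fixed = TRUE)[[1L]]
  expect_equal(int2$neutral_mass, sum(RESIDUE_MASSES[aa[16:18]]),
               tolerance = 1e-9)
  # empty span is degenerate
  expect_error(internal_by_fragments(top, list(c(3, 2)), 1), "spans no")
})

test_that("theoretical spectrum aggregates all ion families sorted by m/z", {
  top <- metanodin_like_topology()
  ts <- theoretical_spectrum(top)
  expect_true(all(diff(ts$mz) >= 0))
  expect_true(all(sprintf("b%d", 10:19) %in% ts$label[ts$kind == "b_tail"]))
  expect_true(all(sprintf("y%d", 1:10) %in% ts$label[ts$kind == "y_tail"]))
  expect_true("(b18y5)" %in% ts$label)   # complement of (b15)*(y2)
  expect_true(all(c("precursor", "b_ring_opened", "interlocked") %in%
                    ts$kind))
  # m/z consistent with neutral mass and charge for every row
  expect_equal(ts$mz, (ts$neutral_mass + ts$z * PROTON_MASS) / ts$z,
               tolerance = 1e-9)
  expect_error(theoretical_spectrum(top, charges = numeric()), "non-empty")
})

test_that("fragment tables round-trip through TSV", {
  ts <- theoretical_spectrum(small_top(), charges = 1:2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_tsv(ts, path)
  back <- read_fragment_tsv(path)
  expect_equal(back$label, ts$label)
  expect_equal(back$mz, ts$mz, tolerance = 1e-5)
})
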