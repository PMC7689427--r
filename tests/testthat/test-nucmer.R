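test_that("percent identity is the match fraction", {
  expect_equal(percent_identity(10000, 1), 99.99)
  expect_equal(percent_identity(c(1, 500, 1e6), 0), c(100, 100, 100))
  expect_equal(percent_identity(20000, 8), 99.96)
  expect_error(percent_identity(0, 0), "aln_length")
  expect_error(percent_identity(100, 101), "mismatches")
})

test_that("length filter keeps >= min_len and preserves order", {
  rec <- alignment_records("c", "c", c(1, 3e4, 7e4), c(9584, 5e4, 95e3),
                           c(1, 3e4, 7e4), c(9584, 5e4, 95e3),
                           aln_length = c(9584, 20000, 25000),
                           mismatches = 0)
  kept <- filter_alignments(rec)
  expect_equal(kept$aln_length, c(20000, 25000))
  expect_equal(nrow(filter_alignments(rec[0, ])), 0L)
  expect_equal(nrow(filter_alignments(rec, min_len = 1)), 3L)
})

test_that("bin assignment follows the reference midpoint rule", {
  mk <- function(s, e) alignment_records("c", "c", s, e, s, e, e - s + 1, 0)
  # midpoints 4,999,999 and 5,000,001 fall either side of the 5-Mbp boundary
  bins <- bin_alignments(rbind(mk(4999998, 5000000), mk(5000000, 5000002)),
                         bin_size = 5e6, chrom_len = 12e6)
  expect_equal(bins$n_aln, c(1L, 1L, 0L))
  # midpoint exactly at the boundary belongs to the closing bin
  bins2 <- bin_alignments(mk(4999999, 5000001), 5e6, 12e6)
  expect_equal(bins2$n_aln[1], 1L)
  # last bin truncation: 12 Mbp at 5 Mbp gives breadths 5, 5, 2 Mbp
  expect_equal(bins$end - bins$start + 1, c(5e6, 5e6, 2e6))
})

test_that("bin medians and aligned bp summarise the assigned alignments", {
  rec <- alignment_records("c", "c", c(1e6, 2e6, 3e6), c(1e6 + 49999, 2e6 + 49999, 3e6 + 49999),
                           c(1e6, 2e6, 3e6), c(1e6 + 49999, 2e6 + 49999, 3e6 + 49999),
                           aln_length = 5e4, mismatches = c(0, 5, 25))
  bins <- bin_alignments(rec, 5e6, 5e6)
  expect_equal(bins$median_identity, stats::median(rec$identity_pct))
  expect_equal(bins$aligned_bp, 15e4)
  expect_equal(bins$breadth_pct, 100 * 15e4 / 5e6)
  one <- bin_alignments(rec[2, ], 5e6, 5e6)
  expect_equal(one$median_identity, rec$identity_pct[2])
  expect_error(bin_alignments(rec, 5e6, chrom_len = 2e6), "midpoint")
})

test_that("stitching matches the documented bin-pattern examples", {
  g <- TRUE; b <- FALSE
  run <- function(pattern) call_blocks(bins_from_pattern(pattern))
  expect_equal(nrow(run(c(g, g, g, g))), 1L)
  expect_equal(run(c(g, g, g, g))$end, 40)

  two_err <- run(c(g, b, b, g))
  expect_equal(nrow(two_err), 1L)         # two errors absorbed
  expect_equal(c(two_err$start, two_err$end), c(1, 40))

  three_err <- run(c(g, b, b, b, g))
  expect_equal(nrow(three_err), 2L)       # three errors split the block
  expect_equal(three_err$start, c(1, 41))
  expect_equal(three_err$end, c(10, 50))

  # empty bins behave as error bins
  expect_equal(nrow(run(c(g, NA, NA, g))), 1L)
  expect_equal(nrow(run(c(g, NA, NA, NA, g))), 2L)
  # blocks start and end on good bins; single good bin is a block
  single <- run(c(b, g, b))
  expect_equal(c(single$start, single$end), c(11, 20))
  expect_equal(nrow(run(c(b, b, b))), 0L)
})

test_that("stitching equals the exhaustive maximal-run oracle on random patterns", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    good <- sample(c(TRUE, FALSE), n, replace = TRUE)
    max_err <- sample(0:3, 1)
    blocks <- call_blocks(bins_from_pattern(good), max_err_run = max_err)
    oracle <- stitch_oracle(good, max_err)
    expect_equal(nrow(blocks), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(blocks$start, (oracle[, 1] - 1) * 10 + 1)
      expect_equal(blocks$end, oracle[, 2] * 10)
    }
  }
})

test_that("threshold comparison is >= with exact decimal semantics", {
  bins <- bins_from_pattern(TRUE)
  bins$median_identity <- 99.99
  expect_equal(nrow(call_blocks(bins, threshold = 99.99)), 1L)
  bins$median_identity <- 99.9899
  expect_equal(nrow(call_blocks(bins, threshold = 99.99)), 0L)
})

test_that("lowering the threshold never loses blocked bp", {
  set.seed(11)
  for (i in 1:20) {
    bins <- bins_from_pattern(sample(c(TRUE, FALSE, NA), 12, replace = TRUE))
    bins$median_identity <- ifelse(is.na(bins$median_identity), NA,
                                   99.9 + stats::runif(12) * 0.1)
    bp <- function(th) {
      b <- call_blocks(bins, threshold = th)
      if (nrow(b) == 0L) 0 else sum(b$end - b$start + 1)
    }
    expect_true(bp(99.95) >= bp(99.99))
  }
})

test_that("called blocks never overlap for a given pair and bin size", {
  set.seed(3)
  for (i in 1:20) {
    good <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    b <- call_blocks(bins_from_pattern(good))
    if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
})

test_that("reciprocal filtering keeps only mutually supported blocks", {
  ab <- blk(start = c(1, 30e6), end = c(10e6, 40e6))
  ba <- blk(start = 5e6, end = 15e6, ref = "B", query = "A")
  res <- reciprocal_consistency(ab, ba)
  expect_equal(res$ab$start, 1)          # overlapping pair retained
  expect_equal(nrow(res$ba), 1L)         # symmetric
  # block only in one direction is dropped
  expect_equal(nrow(reciprocal_consistency(ab[2, ], ba)$ab), 0L)
  # identical sets retained in full
  res2 <- reciprocal_consistency(ab, ab)
  expect_equal(nrow(res2$ab), 2L)
  # failing lifter drops with a warning
  ws <- capture_warnings(
    res3 <- reciprocal_consistency(ab, ba, lift_ab = function(x) NULL))
  expect_match(ws, "lift failed", all = TRUE)
  expect_equal(nrow(res3$ab), 0L)
})

test_that("whole pipeline recovers trivial planted structure", {
  spec0 <- pangenome_spec(n_cultivars = 2, chrom_len = 5e6,
                          planted_blocks = data.frame(cultivars = "cv1;cv2",
                                                      start = 1, end = 5e6),
                          introgressions = NULL, n_runs = NULL,
                          noise_alignments = 0, seed = 5)
  sim0 <- simulate_pangenome(spec0)
  b <- call_pairwise_nucmer(sim0$alignments[["cv1|cv2"]], bin_size = 1e6,
                            chrom_len = 5e6)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(1, 5e6))

  # an all-divergent pair (0.5% divergence) yields no blocks
  spec1 <- pangenome_spec(n_cultivars = 2, chrom_len = 5e6,
                          planted_blocks = NULL,
                          background_divergence = 0.005,
                          introgressions = NULL, n_runs = NULL, seed = 6)
  sim1 <- simulate_pangenome(spec1)
  expect_equal(nrow(call_pairwise_nucmer(sim1$alignments[["cv1|cv2"]],
                                         1e6, chrom_len = 5e6)), 0L)
})
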