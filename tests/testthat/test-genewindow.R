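mk_hsps <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(qseqid = r$q, sseqid = r$s %||% "chr", pident = r$p,
               length = r$l, mismatch = r$m %||% 0, gapopen = 0,
               qstart = 1, qend = r$l, sstart = 1, send = r$l,
               bitscore = r$b %||% 2 * r$l, qNs = r$qn %||% 0,
               sNs = r$sn %||% 0, stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# a filtered gene-alignment table straight from identities
gas_from_ids <- function(ids) {
  data.frame(gene_id = sprintf("g%03d", seq_along(ids)), subject = "chr",
             identity_pct = ids, hsp_length = 3000, contains_n = FALSE,
             ref_rank = seq_along(ids), stringsAsFactors = FALSE)
}

test_that("best HSP selection takes the largest, with documented tie-breaks", {
  ga <- select_best_hsp(mk_hsps(list(q = "g1", p = 99, l = 500),
                                list(q = "g1", p = 100, l = 300)))
  expect_equal(ga$hsp_length, 500)   # largest wins even at lower identity

  single <- select_best_hsp(mk_hsps(list(q = "g2", p = 98, l = 200)))
  expect_equal(single$identity_pct, 98)

  # tie on length: higher bitscore, then higher identity
  tie <- select_best_hsp(mk_hsps(list(q = "g3", p = 97, l = 400, b = 700),
                                 list(q = "g3", p = 99, l = 400, b = 650)))
  expect_equal(tie$identity_pct, 97)
  tie2 <- select_best_hsp(mk_hsps(list(q = "g4", p = 97, l = 400, b = 700),
                                  list(q = "g4", p = 99, l = 400, b = 700)))
  expect_equal(tie2$identity_pct, 99)

  withn <- select_best_hsp(mk_hsps(list(q = "g5", p = 100, l = 100, qn = 2)))
  expect_true(withn$contains_n)
})

test_that("gene-alignment filters drop wrong-chromosome, duplicated and N genes", {
  pr <- gene_projections(c("g1", "g2", "g2", "g3", "g4"), "cvX",
                         chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
                         start = c(100, 200, 300, 400, 500),
                         end = c(150, 250, 350, 450, 550))
  gas <- data.frame(gene_id = c("g1", "g2", "g3", "g4"), subject = "chr1",
                    identity_pct = 100, hsp_length = 100,
                    contains_n = c(FALSE, FALSE, FALSE, TRUE))
  out <- filter_gene_alignments(gas, pr, "chr1")
  # g2 duplicated on chr1, g3 on the wrong chromosome, g4 has Ns
  expect_equal(out$gene_id, "g1")
  clean <- filter_gene_alignments(gas[1, ], pr, "chr1")
  expect_equal(clean$gene_id, "g1")
})

test_that("window scan trims the lowest 10% and demands an exact 100% mean", {
  all100 <- window_scan(gas_from_ids(rep(100, 25)))
  expect_equal(nrow(all100), 1L)
  expect_true(all100$identical)

  # 22 x 100 + 3 x 99.5: the three sub-100 values are exactly the trim
  trimmed <- window_scan(gas_from_ids(c(rep(100, 22), rep(99.5, 3))))
  expect_true(trimmed$identical)

  # 21 x 100 + 4 x 99.9: one sub-100 value survives trimming
  survived <- window_scan(gas_from_ids(c(rep(100, 21), rep(99.9, 4))))
  expect_false(survived$identical)
  expect_equal(survived$trimmed_mean, mean(c(rep(100, 21), 99.9)))

  expect_warning(none <- window_scan(gas_from_ids(rep(100, 10))),
                 "fewer than W")
  expect_equal(nrow(none), 0L)
})

test_that("trim count is ceiling(trim_frac * W) and windows step by one gene", {
  # W = 10, f = 0.10 trims exactly 1; one 99% value is absorbed
  calls <- window_scan(gas_from_ids(c(rep(100, 9), 99, rep(100, 5))), W = 10)
  expect_equal(nrow(calls), 6L)                 # n - W + 1 windows
  expect_true(all(calls$identical))
  # two sub-100 values exceed the single trim slot
  calls2 <- window_scan(gas_from_ids(c(rep(100, 8), 99, 99, rep(100, 10))),
                        W = 10)
  expect_false(any(calls2$identical[1:9]))      # windows containing both 99s
  expect_true(all(calls2$identical[10:11]))     # at most one 99: trimmed away
})

test_that("raising any identity to 100 never breaks an identical window", {
  set.seed(21)
  for (i in 1:25) {
    ids <- sample(c(100, 100, 100, 99.9, 99.5), 25, replace = TRUE)
    before <- window_scan(gas_from_ids(ids))$identical
    j <- sample(25, 1)
    ids[j] <- 100
    after <- window_scan(gas_from_ids(ids))$identical
    expect_true(all(after >= before))
  }
})

test_that("identical windows merge into blocks over terminal gene spans", {
  pr <- gene_projections(sprintf("g%03d", 1:40), "ref", "chr1",
                         start = (1:40) * 1000, end = (1:40) * 1000 + 500)
  gas <- gas_from_ids(rep(100, 40))
  calls <- window_scan(gas, W = 25)
  blocks <- windows_to_blocks(calls, gas, pr, "ref", "ref", "chr1")
  expect_equal(nrow(blocks), 1L)
  expect_equal(c(blocks$start, blocks$end), c(1000, 40500))
  expect_equal(blocks$source, "blast")

  # non-identical windows in the middle split the calls into two runs
  # (two adjacent sub-100 genes exceed the one-slot trim at W = 10)
  ids <- rep(100, 40); ids[20:21] <- 99
  calls2 <- window_scan(gas_from_ids(ids), W = 10)
  blocks2 <- windows_to_blocks(calls2, gas_from_ids(ids), pr, "ref", "ref",
                               "chr1")
  expect_equal(nrow(blocks2), 2L)
  expect_true(blocks2$end[1] < blocks2$start[2])

  none <- window_scan(gas_from_ids(rep(99, 40)), W = 25)
  expect_equal(nrow(windows_to_blocks(none, gas, pr, "ref", "ref", "chr1")),
               0L)
})

test_that("combining keeps binned blocks and non-redundant gene-window blocks", {
  nuc <- blk(start = 10e6, end = 20e6, source = "nucmer", bin_size = 5e6)
  redundant <- blk(start = 12e6, end = 14e6, source = "blast")   # 2 Mbp inside
  novel <- blk(start = 30e6, end = 32e6, source = "blast")       # no overlap
  big <- blk(start = 9e6, end = 19e6, source = "blast")          # >= bin size
  out <- combine_blocks(nuc, rbind(redundant, novel, big))
  expect_equal(nrow(out), 3L)
  expect_false(any(out$start == 12e6))
  expect_true(any(out$start == 30e6))
  expect_true(any(out$start == 9e6))
  expect_equal(combine_blocks(nuc, nuc[0, ]), nuc)
  # coverage of the combined set contains the binned coverage
  expect_true(all(nuc$start %in% out$start))
})

test_that("precision/recall/F1 follow the overlap-count definitions", {
  identical_sets <- precision_recall_f1(blk(1, 10), blk(1, 10))
  expect_equal(unlist(identical_sets[c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))

  pr <- precision_recall_f1(blk(start = c(1, 20), end = c(10, 30)),
                            blk(start = 5, end = 15))
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 1)
  expect_equal(pr$f1, 2 / 3)

  disjoint <- precision_recall_f1(blk(1, 10), blk(20, 30))
  expect_equal(disjoint$f1, 0)

  empty <- precision_recall_f1(blk(1, 10)[0, ], blk(1, 10))
  expect_equal(empty$precision, 0)
  expect_true("precision" %in% empty$undefined)
})

test_that("precision/recall equal brute-force overlap counting on random sets", {
  set.seed(31)
  for (i in 1:50) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    a_start <- sample(1:500, na); b_start <- sample(1:500, nb)
    a <- blk(start = a_start, end = a_start + sample(5:80, na, replace = TRUE))
    b <- blk(start = b_start, end = b_start + sample(5:80, nb, replace = TRUE))
    pr <- precision_recall_f1(a, b)
    expect_equal(pr$precision, overlap_count(a, b) / nrow(a))
    expect_equal(pr$recall, overlap_count(b, a) / nrow(b))
    expect_true(pr$precision >= 0 && pr$precision <= 1)
    expect_true(pr$recall >= 0 && pr$recall <= 1)
  }
})

test_that("parameter sweep scores each configuration and flags the best", {
  pr <- gene_projections(sprintf("g%03d", 1:60), "ref", "chr1",
                         start = (1:60) * 1000, end = (1:60) * 1000 + 500)
  truth <- blk(start = 1000, end = 61000, source = "nucmer", bin_size = 5e6)
  gas <- gas_from_ids(rep(100, 60))
  sweep <- parameter_sweep(list(w10 = gas, w25 = gas), truth,
                           data.frame(label = c("w10", "w25"),
                                      W = c(10, 25), flank = 2000),
                           pr, "ref", "chr1")
  expect_equal(nrow(sweep), 2L)
  expect_equal(sweep$f1, c(1, 1))
  expect_true(attr(sweep, "best") %in% c("w10", "w25"))
})
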