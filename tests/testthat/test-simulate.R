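# block at 25-75% of the chromosome, introgression at 5-15%, one N run
small_spec <- function(seed, chrom_len = 4e6, ...) {
  L <- chrom_len
  pangenome_spec(n_cultivars = 3, chrom_len = L,
                 planted_blocks = data.frame(cultivars = "cv1;cv2",
                                             start = 0.25 * L, end = 0.75 * L),
                 introgressions = data.frame(cultivar = "cv3",
                                             start = 0.05 * L, end = 0.15 * L,
                                             divergence = 0.007),
                 n_runs = data.frame(cultivar = "cv1", start = 0.45 * L,
                                     length = 0.0075 * L),
                 aln_chunk = L / 80, seed = seed, ...)
}

test_that("the spec rejects contradictory constructions", {
  expect_error(pangenome_spec(seed = 1, planted_blocks = data.frame(
    cultivars = c("cv1;cv2", "cv2;cv3"), start = c(1e6, 2e6),
    end = c(3e6, 4e6))), "overlapping planted blocks")
  expect_error(pangenome_spec(seed = 1, planted_blocks = data.frame(
    cultivars = "cv1;cv9", start = 1e6, end = 2e6)), "unknown cultivar")
  expect_error(pangenome_spec(seed = 1, chrom_len = 4e6,
    planted_blocks = data.frame(cultivars = "cv1;cv2", start = 1e6,
                                end = 3e6),
    introgressions = data.frame(cultivar = "cv1", start = 1.5e6, end = 2.5e6,
                                divergence = 0.01)),
    "contradicts")
  expect_error(pangenome_spec(), "seed is mandatory")
})

test_that("zero divergence and two cultivars give one perfect alignment", {
  spec <- pangenome_spec(n_cultivars = 2, chrom_len = 1e6,
                         planted_blocks = NULL, background_divergence = 0,
                         introgressions = NULL, n_runs = NULL,
                         noise_alignments = 0, aln_chunk = 1e7, seed = 2)
  sim <- simulate_pangenome(spec)
  rec <- sim$alignments[["cv1|cv2"]]
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$identity_pct, 100)
  expect_equal(c(rec$ref_start, rec$ref_end), c(1, 1e6))
})

test_that("same spec and seed reproduce byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_pangenome(simulate_pangenome(small_spec(seed = 11)), d1,
                  gene_aln_flank = 2000)
  write_pangenome(simulate_pangenome(small_spec(seed = 11)), d2,
                  gene_aln_flank = 2000)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # a different seed changes the substitution draw
  sim_a <- simulate_pangenome(small_spec(seed = 11))
  sim_b <- simulate_pangenome(small_spec(seed = 12))
  expect_false(identical(sim_a$alignments[["cv1|cv2"]]$mismatches,
                         sim_b$alignments[["cv1|cv2"]]$mismatches))
})

test_that("expected_mismatches gives the binomial mean and interval", {
  em <- expected_mismatches(3.2e-4, 1e6)
  expect_equal(em$mean, 320)
  expect_true(em$lower < 320 && em$upper > 320)
  expect_equal(expected_mismatches(0, 1e6)$mean, 0)
  expect_equal(expected_mismatches(0.5, 0)$mean, 0)
})

test_that("background mismatch rates are calibrated to the spec divergence", {
  for (seed in c(31, 32, 33)) {
    spec <- pangenome_spec(n_cultivars = 2, chrom_len = 5e6,
                           planted_blocks = NULL, introgressions = NULL,
                           n_runs = NULL, noise_alignments = 0,
                           aln_chunk = 1e7, seed = seed)
    sim <- simulate_pangenome(spec)
    rec <- sim$alignments[["cv1|cv2"]]
    em <- expected_mismatches(spec$background_divergence, sum(rec$aln_length))
    expect_true(sum(rec$mismatches) >= em$lower &&
                  sum(rec$mismatches) <= em$upper)
  }
})

test_that("planted blocks are perfectly identical and recovered by the caller", {
  sim <- simulate_pangenome(small_spec(seed = 41))
  rec <- sim$alignments[["cv1|cv2"]]
  # real alignments fully inside the planted block carry zero mismatches
  # (noise records below the 20-kb filter are excluded)
  inside <- rec$ref_start >= 1e6 & rec$ref_end <= 3e6 &
    rec$aln_length >= 20000
  expect_true(any(inside))
  expect_true(all(rec$mismatches[inside] == 0))
  # N run interrupts alignments: no record crosses it
  expect_false(any(rec$ref_start < 1.8e6 & rec$ref_end >= 1.8e6))

  called <- call_pairwise_nucmer(rec, bin_size = 2.5e5, chrom_len = 4e6,
                                 min_aln_len = 20000)
  truth <- blk(sim$truth$start, sim$truth$end)
  expect_true(jaccard_bp(called, truth) >= 0.9)
})

test_that("alignment records agree with materialised sequences", {
  spec <- small_spec(seed = 51, chrom_len = 5e5)
  sim <- simulate_pangenome(spec, emit_sequences = TRUE)
  s1 <- strsplit(sim$sequences[["cv1"]], "")[[1]]
  s2 <- strsplit(sim$sequences[["cv2"]], "")[[1]]
  rec <- sim$alignments[["cv1|cv2"]]
  rec <- rec[rec$aln_length >= 20000, ]  # skip noise records
  for (i in seq_len(nrow(rec))) {
    seg <- rec$ref_start[i]:rec$ref_end[i]
    expect_equal(sum(s1[seg] != s2[seg]), rec$mismatches[i])
    expect_false(any(s1[seg] == "N") || any(s2[seg] == "N"))
  }
  # SNP records match sequence differences outside N runs
  snps <- sim$snps[["cv2"]]
  ok <- snps$ref_allele != "N" & snps$alt_allele != "N"
  expect_true(all(s1[snps$ref_pos[ok]] == snps$ref_allele[ok]))
  expect_true(all(s2[snps$ref_pos[ok]] == snps$alt_allele[ok]))
})

test_that("genotype matrix separates planted haplotype groups", {
  sim <- simulate_pangenome(small_spec(seed = 61))
  gm <- sim$genotypes
  expect_s3_class(gm, "genotype_matrix")
  # cv1 and cv2 share the planted block: identical calls at block markers
  in_block <- gm$markers$pos >= 1e6 & gm$markers$pos <= 3e6
  expect_true(any(in_block))
  same <- gm$calls["cv1", in_block] == gm$calls["cv2", in_block]
  expect_true(all(same[!is.na(same)]))
  expect_equal(unname(sim$groups["cv1"]), unname(sim$groups["cv2"]))
  expect_false(sim$groups[["cv3"]] == sim$groups[["cv1"]])
})

test_that("gene alignment tables carry exact per-window mismatches and Ns", {
  spec <- small_spec(seed = 71, chrom_len = 5e5)
  sim <- simulate_pangenome(spec, emit_sequences = TRUE)
  ga <- simulate_gene_alignments(sim, "cv1", "cv2", flank = 1000)
  s1 <- strsplit(sim$sequences[["cv1"]], "")[[1]]
  s2 <- strsplit(sim$sequences[["cv2"]], "")[[1]]
  for (i in sample(nrow(ga), 10)) {
    seg <- ga$sstart[i]:ga$send[i]
    diffs <- sum(s1[seg] != s2[seg] & s1[seg] != "N" & s2[seg] != "N")
    expect_equal(ga$mismatch[i], diffs)
    expect_equal(ga$qNs[i], sum(s1[seg] == "N"))
  }
  # flankless alignments are blind to intergenic background divergence
  ga0 <- simulate_gene_alignments(sim, "cv1", "cv3", flank = 0)
  ga2 <- simulate_gene_alignments(sim, "cv1", "cv3", flank = 2000)
  outside_intro <- ga0$sstart > 0.15 * 5e5 | ga0$send < 0.05 * 5e5
  expect_true(mean(ga0$pident[outside_intro] == 100) >
                mean(ga2$pident[outside_intro] == 100))
})
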