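# Shared fixtures and independent oracles used across test files.

# bp-level Jaccard index between two block tables (single chromosome)
jaccard_bp <- function(a, b) {
  ir <- function(df) IRanges::reduce(IRanges::IRanges(df$start, df$end))
  ia <- ir(a); ib <- ir(b)
  inter <- sum(IRanges::width(IRanges::intersect(ia, ib)))
  un <- sum(IRanges::width(IRanges::union(ia, ib)))
  if (un == 0) return(1)
  inter / un
}

# blocks helper with minimal ceremony
blk <- function(start, end, ref = "A", query = "B", chrom = "chr",
                source = "nucmer", bin_size = NA_real_) {
  haplotype_blocks(ref, query, chrom, start, end, source, bin_size)
}

# build a bin table directly from a good/bad pattern (TRUE = good bin):
# good bins get median 100, bad bins 99.9, NA bins stay empty
bins_from_pattern <- function(pattern, bin_size = 10) {
  n <- length(pattern)
  data.frame(index = seq_len(n),
             start = (seq_len(n) - 1) * bin_size + 1,
             end = seq_len(n) * bin_size,
             n_aln = ifelse(is.na(pattern), 0L, 5L),
             median_identity = ifelse(is.na(pattern), NA_real_,
                                      ifelse(pattern, 100, 99.9)),
             aligned_bp = 0, breadth_pct = 0)
}

# independent stitching oracle: enumerate every candidate sub-run
# [i, j] of the bin vector and keep the maximal valid ones. Valid: good at
# both ends and no internal run of non-good bins longer than max_err.
stitch_oracle <- function(good, max_err = 2) {
  n <- length(good)
  valid <- function(i, j) {
    if (!good[i] || !good[j]) return(FALSE)
    r <- rle(good[i:j])
    bad_runs <- r$lengths[!r$values]
    length(bad_runs) == 0L || max(bad_runs) <= max_err
  }
  cand <- list()
  for (i in seq_len(n)) for (j in i:n)
    if (valid(i, j)) cand[[length(cand) + 1L]] <- c(i, j)
  if (length(cand) == 0L) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, cand)
  maximal <- vapply(seq_len(nrow(m)), function(k) {
    !any(m[, 1] <= m[k, 1] & m[, 2] >= m[k, 2] &
           (m[, 1] != m[k, 1] | m[, 2] != m[k, 2]))
  }, logical(1))
  m[maximal, , drop = FALSE]
}

# brute-force interval overlap counters for precision/recall
overlap_count <- function(a, b) {
  sum(vapply(seq_len(nrow(a)), function(i)
    any(a$start[i] <= b$end & a$end[i] >= b$start), logical(1)))
}

# small deterministic genotype fixture: 4 groups over 12 markers
toy_genotypes <- function() {
  markers <- data.frame(marker_id = sprintf("m%02d", 1:12), chrom = "chr6A",
                        pos = seq(190e6, 440e6, length.out = 12))
  prof <- rbind(
    H1 = c(0,0,0,0, 0,0,0,0, 0,0,0,0),
    H2 = c(1,1,1,0, 0,0,0,0, 0,0,0,1),
    H3 = c(1,1,0,1, 1,1,0,0, 0,1,1,1),
    H4 = c(0,0,1,1, 1,1,1,1, 1,1,0,0))
  lines <- prof[rep(1:4, each = 2), ]
  rownames(lines) <- paste0(rep(rownames(prof), each = 2), c("_a", "_b"))
  colnames(lines) <- markers$marker_id
  genotype_matrix(lines, markers)
}
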