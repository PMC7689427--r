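# Sequence-level utilities: expected identity under a molecular clock, k-mer
# Shannon complexity of SNP-flanking sequence, SNP collation across pairwise
# comparisons, and breadth/identity reports for targeted regions.

#' Expected percent identity after a given divergence time
#'
#' Two lineages splitting t years ago each accumulate substitutions at
#' \code{rate} per nucleotide per year, so pairwise identity is
#' \code{100 * (1 - 2 * rate * years)}, floored at 0. At the wheat
#' repetitive/intergenic rate of 1.6e-8 nt^-1 yr^-1, 10,000 years of
#' divergence gives 99.968% — the yardstick separating near-identical
#' haplotypes from identical-by-state ones.
#'
#' @param rate substitution rate per nucleotide per year (>= 0).
#' @param years divergence time in years (>= 0).
#' @return expected identity in percent.
#' @export
expected_identity <- function(rate, years) {
  stopifnot(all(rate >= 0), all(years >= 0))
  pmax(0, 100 * (1 - 2 * rate * years))
}

#' Shannon k-mer richness (effective number of k-mers)
#'
#' Counts all overlapping k-mers of the sequence, forms frequencies p_i and
#' returns \code{exp(-sum(p_i * log(p_i)))} — the effective number of k-mer
#' species, between 1 (homopolymer) and \code{min(4^k, n_kmers)}. With
#' \code{as_entropy = TRUE} the natural-log entropy H is returned instead.
#'
#' @param seq DNA string (A/C/G/T only; N must be filtered upstream).
#' @param k k-mer size (default 2).
#' @param as_entropy return H rather than exp(H).
#' @return numeric scalar.
#' @export
kmer_shannon_richness <- function(seq, k = 2, as_entropy = FALSE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k")
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT characters; filter Ns upstream")
  kmers <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  p <- table(kmers) / length(kmers)
  h <- -sum(p * log(p))
  if (as_entropy) h else exp(h)
}

#' Extract fixed-width flanks around SNPs from an assembly sequence
#'
#' Returns the 2*flank+1 window centred on each SNP. SNPs too close to a
#' sequence end are dropped with a warning; windows containing N are excluded
#' (complexity is undefined over Ns).
#'
#' @param snps SNP table from [snp_records()].
#' @param assembly_seq named character vector of chromosome sequences
#'   (names match \code{ref_chrom}).
#' @param flank flank width in bp (default 10).
#' @return the surviving SNP rows with \code{flank_seq} filled in.
#' @export
snp_flank_extract <- function(snps, assembly_seq, flank = 10) {
  keep <- logical(nrow(snps))
  seqs <- character(nrow(snps))
  n_edge <- 0L
  for (i in seq_len(nrow(snps))) {
    chrom_seq <- assembly_seq[[snps$ref_chrom[i]]]
    if (is.null(chrom_seq)) next
    pos <- snps$ref_pos[i]
    if (pos - flank < 1 || pos + flank > nchar(chrom_seq)) {
      n_edge <- n_edge + 1L
      next
    }
    s <- substr(chrom_seq, pos - flank, pos + flank)
    if (grepl("N", s, fixed = TRUE)) next
    keep[i] <- TRUE
    seqs[i] <- s
  }
  if (n_edge > 0L)
    warning(n_edge, " SNP(s) closer than ", flank, " bp to a sequence end; dropped")
  out <- snps[keep, , drop = FALSE]
  out$flank_seq <- seqs[keep]
  rownames(out) <- NULL
  out
}

#' Collate SNPs across pairwise comparisons
#'
#' Removes records whose reference or alternative allele is "N" or "." and
#' deduplicates by reference position (first occurrence kept), yielding the
#' union SNP set across all pairwise comparisons.
#'
#' @param per_pair_snps list of SNP tables ([snp_records()]), one per pairwise
#'   comparison, or a single combined table.
#' @return deduplicated SNP table.
#' @export
collate_snps <- function(per_pair_snps) {
  if (is.data.frame(per_pair_snps)) per_pair_snps <- list(per_pair_snps)
  all <- do.call(rbind, per_pair_snps)
  if (is.null(all) || nrow(all) == 0L)
    return(snp_records(character(0), numeric(0), character(0), character(0),
                       character(0)))
  bad <- all$ref_allele %in% c("N", ".") | all$alt_allele %in% c("N", ".")
  all <- all[!bad, , drop = FALSE]
  key <- paste(all$ref_chrom, all$ref_pos)
  out <- all[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Breadth/identity report for a targeted region alignment
#'
#' From per-region tallies: maximum alignable sequence = total - Ns; total
#' aligned = matched + mismatch/indel columns; identity = 100 * matched /
#' total aligned; breadth = 100 * total aligned / maximum alignable.
#' Percentages are reported to 1 decimal place in \code{print()}.
#'
#' @param total total sequence queried, bp.
#' @param n_count N positions, bp.
#' @param matched matched columns, bp.
#' @param mismatch_indel SNP plus small-indel columns, bp.
#' @return object of class \code{"region_report"} (a list of the tallies and
#'   derived \code{max_alignable}, \code{total_aligned}, \code{identity_pct},
#'   \code{breadth_pct}; \code{identity_pct} is NA, with
#'   \code{identity_defined = FALSE}, when nothing aligned).
#' @export
region_identity_report <- function(total, n_count, matched, mismatch_indel) {
  stopifnot(total >= 0, n_count >= 0, matched >= 0, mismatch_indel >= 0)
  max_alignable <- total - n_count
  total_aligned <- matched + mismatch_indel
  if (total_aligned > max_alignable)
    stop("total aligned exceeds maximum alignable sequence")
  defined <- total_aligned > 0
  structure(list(
    total = total, n_count = n_count, max_alignable = max_alignable,
    matched = matched, mismatch_indel = mismatch_indel,
    total_aligned = total_aligned,
    identity_pct = if (defined) 100 * matched / total_aligned else NA_real_,
    breadth_pct = if (max_alignable > 0) 100 * total_aligned / max_alignable
    else NA_real_,
    identity_defined = defined
  ), class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat("region alignment report\n")
  cat(sprintf("  total sequence      %12.0f bp (Ns: %.0f)\n", x$total, x$n_count))
  cat(sprintf("  maximum alignable   %12.0f bp\n", x$max_alignable))
  cat(sprintf("  total aligned       %12.0f bp  breadth %.1f%%\n",
              x$total_aligned, x$breadth_pct))
  if (x$identity_defined)
    cat(sprintf("  matched             %12.0f bp  identity %.1f%%\n",
                x$matched, x$identity_pct))
  else cat("  identity undefined (nothing aligned)\n")
  invisible(x)
}

#' Compare SNP-flank complexity inside vs outside haplotype blocks
#'
#' Labels each SNP by block membership for the given pairwise block set,
#' computes k-mer Shannon richness of its flank, subsamples up to
#' \code{subsample} SNPs per category under the given seed, and compares the
#' two groups with a rank-sum test (BH-adjustable by the caller across
#' pairwise comparisons).
#'
#' @param flanks SNP table with \code{flank_seq} filled (see
#'   [snp_flank_extract()]).
#' @param blocks block table in the same reference coordinates.
#' @param k k-mer size (default 2).
#' @param subsample per-category subsample size (default 10000; smaller
#'   categories are used whole).
#' @param seed RNG seed for the subsampling.
#' @return list with \code{inside}, \code{outside} (complexity vectors),
#'   \code{p_value} (NA with \code{note} when a category is empty).
#' @export
complexity_by_block_status <- function(flanks, blocks, k = 2,
                                       subsample = 10000, seed = 1) {
  if (nrow(flanks) == 0L)
    return(list(inside = numeric(0), outside = numeric(0), p_value = NA_real_,
                note = "no SNPs"))
  in_block <- logical(nrow(flanks))
  for (i in seq_len(nrow(blocks))) {
    in_block <- in_block |
      (flanks$ref_chrom == blocks$chrom[i] &
         flanks$ref_pos >= blocks$start[i] & flanks$ref_pos <= blocks$end[i])
  }
  cx <- vapply(flanks$flank_seq, kmer_shannon_richness, numeric(1), k = k,
               USE.NAMES = FALSE)
  pick <- function(v) {
    if (length(v) <= subsample) return(v)
    v[sample.int(length(v), subsample)]
  }
  set.seed(seed)
  inside <- pick(cx[in_block])
  outside <- pick(cx[!in_block])
  if (length(inside) == 0L || length(outside) == 0L)
    return(list(inside = inside, outside = outside, p_value = NA_real_,
                note = "a category is empty; no test performed"))
  p <- suppressWarnings(stats::wilcox.test(inside, outside)$p.value)
  list(inside = inside, outside = outside, p_value = p, note = NULL)
}
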