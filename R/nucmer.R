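# Binned-identity haplotype block caller for whole-chromosome alignments.
#
# Pipeline: filter alignments by length (default >= 20 kb, excluding short
# retrotransposon-driven alignments), compute per-alignment identity, bin by
# reference midpoint (default 5-Mbp bins), call a bin identical-by-state when
# its median identity >= 99.99%, and stitch adjacent qualifying bins while
# absorbing runs of at most two sub-threshold or empty bins.

.IDENTITY_EPS <- 1e-9

#' Percent sequence identity of an alignment
#'
#' Identity is the match fraction \code{100 * (1 - mismatches/aln_length)}.
#' One mismatch per 10 kb corresponds to 99.99\%, the identical-by-state
#' threshold of the binned caller.
#'
#' @param aln_length alignment length in bp (>= 1).
#' @param mismatches mismatch count in \code{[0, aln_length]}.
#' @return identity in percent, vectorised.
#' @export
percent_identity <- function(aln_length, mismatches) {
  if (any(aln_length < 1)) stop("aln_length must be >= 1")
  if (any(mismatches < 0) || any(mismatches > aln_length))
    stop("mismatches must lie in [0, aln_length]")
  100 * (1 - mismatches / aln_length)
}

#' Filter alignment records by minimum length
#'
#' @param records table from [alignment_records()].
#' @param min_len minimum alignment length in bp (default 20000, which removes
#'   short non-syntenic repeat alignments with a median length near 9.6 kb in
#'   wheat).
#' @return the surviving records, input order preserved.
#' @export
filter_alignments <- function(records, min_len = 20000) {
  records[records$aln_length >= min_len, , drop = FALSE]
}

#' Bin alignments along the reference chromosome
#'
#' Each alignment is assigned to exactly one fixed-width bin by its reference
#' midpoint \code{floor((ref_start + ref_end)/2)}, so an alignment contributes
#' its identity value once; bin i spans \code{[(i-1)*B + 1, i*B]} (the last bin
#' is truncated at \code{chrom_len}).
#'
#' @param records alignment records for one (chromosome, cultivar pair).
#' @param bin_size bin width B in bp (the published resolutions are 5e6, 2.5e6
#'   and 1e6).
#' @param chrom_len chromosome length in bp; every bin up to
#'   \code{ceiling(chrom_len/bin_size)} is present, possibly empty.
#' @return a \code{data.frame} with one row per bin: \code{index}, \code{start},
#'   \code{end}, \code{n_aln}, \code{median_identity} (NA when empty),
#'   \code{aligned_bp} (total reference span of assigned alignments) and
#'   \code{breadth_pct} (\code{100 * aligned_bp / bin width}). The per-bin
#'   identity multisets are attached as the \code{"identities"} attribute.
#' @export
bin_alignments <- function(records, bin_size, chrom_len) {
  n_bins <- ceiling(chrom_len / bin_size)
  mid <- floor((records$ref_start + records$ref_end) / 2)
  if (any(mid > chrom_len))
    stop("alignment midpoint beyond chrom_len")
  idx <- pmax(1L, ceiling(mid / bin_size))
  start <- (seq_len(n_bins) - 1) * bin_size + 1
  end <- pmin(seq_len(n_bins) * bin_size, chrom_len)
  ids <- split(records$identity_pct, factor(idx, levels = seq_len(n_bins)))
  span <- records$ref_end - records$ref_start + 1
  aligned <- vapply(split(span, factor(idx, levels = seq_len(n_bins))), sum,
                    numeric(1))
  bins <- data.frame(
    index = seq_len(n_bins), start = start, end = end,
    n_aln = lengths(ids),
    median_identity = vapply(ids, function(v)
      if (length(v)) stats::median(v) else NA_real_, numeric(1)),
    aligned_bp = as.numeric(aligned), stringsAsFactors = FALSE
  )
  bins$breadth_pct <- 100 * bins$aligned_bp / (bins$end - bins$start + 1)
  attr(bins, "identities") <- ids
  rownames(bins) <- NULL
  bins
}

.good_bins <- function(bins, threshold) {
  !is.na(bins$median_identity) &
    bins$median_identity >= threshold - .IDENTITY_EPS
}

#' Stitch identical-by-state bins into haplotype blocks
#'
#' A bin is "good" when its median identity is defined and at or above the
#' threshold. A block is a maximal run of bins that starts and ends on good
#' bins and in which every internal run of non-good bins (sub-threshold or
#' empty) has length at most \code{max_err_run}. Empty bins count as errors so
#' that N-induced alignment gaps inside a true block are absorbed. A single
#' good bin forms a valid block.
#'
#' @param bins table from [bin_alignments()], sorted by index.
#' @param threshold identical-by-state median-identity threshold in percent
#'   (default 99.99).
#' @param max_err_run maximum run of consecutive sub-threshold bins absorbed
#'   inside a block (default 2).
#' @param ref_cultivar,query_cultivar,chrom labels stamped on the blocks.
#' @return a [haplotype_blocks()] table (source \code{"nucmer"}); block bounds
#'   are the genomic bounds of the first and last good bin.
#' @export
call_blocks <- function(bins, threshold = 99.99, max_err_run = 2,
                        ref_cultivar = "ref", query_cultivar = "query",
                        chrom = "chr") {
  if (is.unsorted(bins$index)) stop("bins must be sorted by index")
  good <- which(.good_bins(bins, threshold))
  if (length(good) == 0L) return(empty_blocks())
  gaps <- diff(good) - 1L           # non-good bins between consecutive good bins
  brk <- c(0L, which(gaps > max_err_run), length(good))
  starts <- good[brk[-length(brk)] + 1L]
  ends <- good[brk[-1L]]
  bin_size <- bins$end[1] - bins$start[1] + 1
  haplotype_blocks(ref_cultivar, query_cultivar, chrom,
                   start = bins$start[starts], end = bins$end[ends],
                   source = "nucmer", bin_size = bin_size)
}

#' Keep only blocks supported by both reciprocal alignments
#'
#' A block called with A as reference is retained iff, after lifting into B
#' coordinates, it overlaps (>= 1 bp) some block called with B as reference;
#' and symmetrically. Blocks whose lift fails are dropped with a warning.
#'
#' @param blocks_ab,blocks_ba block tables for the two orientations of one
#'   cultivar pair and chromosome.
#' @param lift_ab,lift_ba functions mapping a \code{(start, end)} interval into
#'   the other assembly's coordinates, returning \code{c(start, end)} or NULL
#'   on failure. Defaults are identity lifts (collinear assemblies).
#' @return list with elements \code{ab} and \code{ba}, the retained blocks.
#' @export
reciprocal_consistency <- function(blocks_ab, blocks_ba,
                                   lift_ab = identity_lift,
                                   lift_ba = identity_lift) {
  keep_side <- function(blocks, other, lift) {
    if (nrow(blocks) == 0L || nrow(other) == 0L)
      return(blocks[integer(0), , drop = FALSE])
    keep <- logical(nrow(blocks))
    for (i in seq_len(nrow(blocks))) {
      li <- lift(c(blocks$start[i], blocks$end[i]))
      if (is.null(li)) {
        warning("lift failed for block ", blocks$start[i], "-", blocks$end[i],
                "; dropped")
        next
      }
      keep[i] <- any(li[1] <= other$end & li[2] >= other$start)
    }
    blocks[keep, , drop = FALSE]
  }
  list(ab = keep_side(blocks_ab, blocks_ba, lift_ab),
       ba = keep_side(blocks_ba, blocks_ab, lift_ba))
}

#' Identity coordinate lift (collinear assemblies)
#' @param interval numeric \code{c(start, end)}.
#' @return the same interval.
#' @export
identity_lift <- function(interval) interval

#' Call pairwise haplotype blocks from whole-chromosome alignments
#'
#' Convenience pipeline: [filter_alignments()] then [bin_alignments()] then
#' [call_blocks()].
#'
#' @inheritParams call_blocks
#' @inheritParams bin_alignments
#' @param records alignment records for one chromosome and ordered pair.
#' @param min_aln_len minimum alignment length (default 20000 bp).
#' @return a [haplotype_blocks()] table.
#' @export
call_pairwise_nucmer <- function(records, bin_size = 5e6, threshold = 99.99,
                                 max_err_run = 2, chrom_len,
                                 min_aln_len = 20000,
                                 ref_cultivar = "ref", query_cultivar = "query",
                                 chrom = "chr") {
  kept <- filter_alignments(records, min_aln_len)
  bins <- bin_alignments(kept, bin_size, chrom_len)
  call_blocks(bins, threshold, max_err_run, ref_cultivar, query_cultivar,
              chrom)
}
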