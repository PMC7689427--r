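# Haplotype sharing and conservation summaries. Interval arithmetic (union,
# coverage, slicing) is delegated to IRanges, the same machinery the field
# uses for this step; the quantities layered on top (shared fraction,
# partner-coverage profiles, highly conserved regions, 500-kb block sampling,
# compartment summaries) are computed here.

#' Percent of the reference genome shared within blocks for one pair
#'
#' 100 * (bp of the union of the pair's blocks) / (total reference size).
#' Invariant to splitting a block into adjacent sub-blocks.
#'
#' @param blocks block table for one ordered pair, reference coordinates.
#' @param ref_sizes named numeric vector, chromosome -> length in bp. The
#'   denominator is the sum over all supplied chromosomes.
#' @return shared percentage.
#' @export
pairwise_shared_fraction <- function(blocks, ref_sizes) {
  total <- sum(ref_sizes)
  if (nrow(blocks) == 0L) return(0)
  covered <- 0
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    covered <- covered + sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(b$start, b$end))))
  }
  100 * covered / total
}

#' Partner-coverage profile for one reference cultivar
#'
#' For each position of the reference cultivar's chromosome, the number of
#' other cultivars sharing a called block there. Each partner contributes at
#' most 1 per position (its blocks are unioned first).
#'
#' @param all_pair_blocks block table across pairs; rows with
#'   \code{ref_cultivar == reference} are used.
#' @param reference the reference cultivar.
#' @param chrom chromosome to profile.
#' @param chrom_len chromosome length in bp.
#' @return object of class \code{"coverage_profile"}: data frame of maximal
#'   intervals (\code{start}, \code{end}, \code{coverage}) partitioning
#'   \code{[1, chrom_len]}, plus attributes \code{chrom_len}, \code{reference},
#'   \code{chrom}.
#' @export
coverage_profile <- function(all_pair_blocks, reference, chrom, chrom_len) {
  b <- all_pair_blocks[all_pair_blocks$ref_cultivar == reference &
                         all_pair_blocks$chrom == chrom, , drop = FALSE]
  ir <- IRanges::IRanges(numeric(0), numeric(0))
  for (q in unique(b$query_cultivar)) {
    qb <- b[b$query_cultivar == q, , drop = FALSE]
    ir <- c(ir, IRanges::reduce(IRanges::IRanges(qb$start, qb$end)))
  }
  cov <- IRanges::coverage(ir, width = chrom_len)
  df <- data.frame(start = cumsum(c(1, S4Vectors::runLength(cov)))[
    seq_along(S4Vectors::runLength(cov))],
    end = cumsum(S4Vectors::runLength(cov)),
    coverage = S4Vectors::runValue(cov))
  structure(df, class = c("coverage_profile", "data.frame"),
            chrom_len = chrom_len, reference = reference, chrom = chrom)
}

#' Fraction of the chromosome inside at least one block
#' @param profile a [coverage_profile()].
#' @return percent of positions with coverage >= 1.
#' @export
shared_with_any_pct <- function(profile) {
  w <- profile$end - profile$start + 1
  100 * sum(w[profile$coverage >= 1]) / attr(profile, "chrom_len")
}

#' Highly conserved regions of a coverage profile
#'
#' Maximal intervals whose partner coverage is at least \code{min_partners}
#' (default 5, i.e. the haplotype is shared among at least 6 cultivars
#' counting the reference). Positions are also reported scaled to percent of
#' chromosome length for cross-cultivar comparison.
#'
#' @param profile a [coverage_profile()].
#' @param min_partners coverage threshold (default 5).
#' @return data frame \code{start}, \code{end}, \code{pct_start},
#'   \code{pct_end}.
#' @export
conserved_regions <- function(profile, min_partners = 5) {
  keep <- profile$coverage >= min_partners
  if (!any(keep))
    return(data.frame(start = numeric(0), end = numeric(0),
                      pct_start = numeric(0), pct_end = numeric(0)))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  i <- which(r$values)
  out <- data.frame(start = profile$start[starts[i]],
                    end = profile$end[ends[i]])
  len <- attr(profile, "chrom_len")
  out$pct_start <- 100 * out$start / len
  out$pct_end <- 100 * out$end / len
  out
}

#' Sample blocks at fixed 500-kb positions
#'
#' Sampling points sit at \code{step, 2*step, ...} along the chromosome; a
#' block is recorded at every point it intersects (\code{start <= point <=
#' end}), so a 5-Mbp block appears at 10-12 points depending on phase. Each
#' sample carries the block's length, its gene content (reference genes fully
#' contained in the block span) and the point's position as a percent of
#' chromosome length.
#'
#' @param blocks block table in reference coordinates.
#' @param gene_index [gene_projections()] table of the reference annotation
#'   (used for gene counts; may be an empty table).
#' @param chrom_len chromosome length in bp.
#' @param step sampling interval in bp (default 5e5).
#' @return data frame \code{sample_pos}, \code{pct_pos}, \code{block_length},
#'   \code{gene_count}, \code{block_id}.
#' @export
sample_blocks <- function(blocks, gene_index, chrom_len, step = 5e5) {
  points <- seq(step, chrom_len, by = step)
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$start[i]; e <- blocks$end[i]
    hit <- points[points >= s & points <= e]
    if (length(hit) == 0L) next
    gi <- gene_index[gene_index$chrom == blocks$chrom[i], , drop = FALSE]
    ng <- sum(gi$start >= s & gi$end <= e)
    out[[length(out) + 1L]] <- data.frame(
      sample_pos = hit, pct_pos = 100 * hit / chrom_len,
      block_length = e - s + 1, gene_count = ng, block_id = i)
  }
  if (length(out) == 0L)
    return(data.frame(sample_pos = numeric(0), pct_pos = numeric(0),
                      block_length = numeric(0), gene_count = numeric(0),
                      block_id = integer(0)))
  do.call(rbind, out)
}

#' Build a compartment map
#'
#' @param chrom chromosome id.
#' @param boundaries numeric vector of 4 internal boundaries (bp) splitting the
#'   chromosome into R1, R2a, C, R2b, R3 in order.
#' @param chrom_len chromosome length.
#' @return data frame \code{chrom}, \code{compartment}, \code{start},
#'   \code{end}.
#' @export
compartment_map <- function(chrom, boundaries, chrom_len) {
  stopifnot(length(boundaries) == 4, !is.unsorted(boundaries),
            boundaries[4] < chrom_len)
  starts <- c(1, boundaries + 1)
  ends <- c(boundaries, chrom_len)
  data.frame(chrom = chrom, compartment = c("R1", "R2a", "C", "R2b", "R3"),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Summarise block samples per 1% position bin and per compartment
#'
#' Per chromosome, sample values are medianised in 1% position bins; the 1%
#' bins are then assigned to compartments and compartment medians are taken
#' over the chromosome-level bin medians, while compartment min/max come from
#' the raw sample values.
#'
#' @param samples data frame from [sample_blocks()] with an additional
#'   \code{chrom} column (added by the caller when pooling chromosomes), or a
#'   single-chromosome table and \code{chrom} supplied.
#' @param cmap [compartment_map()] rows covering every sampled chromosome.
#' @param value name of the summarised column, \code{"block_length"} (default)
#'   or \code{"gene_count"}.
#' @param chrom chromosome id when \code{samples} lacks a \code{chrom} column.
#' @return list with \code{bins} (per-chromosome 1% bin medians) and
#'   \code{compartments} (median/min/max per compartment).
#' @export
compartment_summary <- function(samples, cmap, value = "block_length",
                                chrom = NULL) {
  if (!"chrom" %in% names(samples)) {
    stopifnot(!is.null(chrom))
    samples$chrom <- chrom
  }
  samples$pct_bin <- pmin(100, ceiling(samples$pct_pos))
  bins <- stats::aggregate(samples[[value]],
                           by = list(chrom = samples$chrom,
                                     pct_bin = samples$pct_bin),
                           FUN = stats::median)
  names(bins)[3] <- "median_value"
  # assign each 1% bin of each chromosome to its compartment by bin midpoint
  bins$compartment <- NA_character_
  samples$compartment <- NA_character_
  for (ch in unique(bins$chrom)) {
    cm <- cmap[cmap$chrom == ch, , drop = FALSE]
    if (nrow(cm) == 0L) stop("no compartment map for chromosome ", ch)
    clen <- max(cm$end)
    i <- which(bins$chrom == ch)
    mid_bp <- (bins$pct_bin[i] - 0.5) / 100 * clen
    k <- findInterval(mid_bp, cm$start)
    bins$compartment[i] <- cm$compartment[pmax(1, k)]
    j <- which(samples$chrom == ch)
    ks <- findInterval(samples$sample_pos[j], cm$start)
    samples$compartment[j] <- cm$compartment[pmax(1, ks)]
  }
  comp <- do.call(rbind, lapply(split(bins, bins$compartment), function(b) {
    raw <- samples[[value]][samples$compartment == b$compartment[1]]
    data.frame(compartment = b$compartment[1],
               median = stats::median(b$median_value),
               min = if (length(raw)) min(raw) else NA_real_,
               max = if (length(raw)) max(raw) else NA_real_,
               n_bins = nrow(b), stringsAsFactors = FALSE)
  }))
  rownames(comp) <- NULL
  list(bins = bins, compartments = comp)
}

#' Compare a sampled value between compartment groups
#'
#' Delegates to pairwise rank-sum tests with Benjamini-Hochberg adjustment.
#'
#' @param samples table from [sample_blocks()] with a \code{compartment}
#'   column (e.g. from [compartment_summary()]'s assignment, or added by the
#'   caller).
#' @param value column to compare.
#' @return data frame of pairwise comparisons with adjusted p values.
#' @export
compare_compartments <- function(samples, value = "block_length") {
  comps <- unique(samples$compartment)
  if (length(comps) < 2) return(data.frame())
  pairs <- utils::combn(sort(comps), 2)
  p <- apply(pairs, 2, function(pr) {
    x <- samples[[value]][samples$compartment == pr[1]]
    y <- samples[[value]][samples$compartment == pr[2]]
    if (length(x) == 0 || length(y) == 0) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  })
  data.frame(a = pairs[1, ], b = pairs[2, ], p = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}
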