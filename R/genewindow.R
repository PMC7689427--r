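# Gene-anchored haplotype block caller. Per-gene best-HSP BLAST alignments
# (gene body +/- flanking sequence) are ordered by reference gene rank and
# scanned with a sliding window; a window is identical-by-state when, after
# dropping the lowest-identity 10% of its alignments, the mean of the rest is
# exactly 100%. Runs of identical windows become blocks, lifted into the
# target assembly's coordinates. This route covers scaffold-level assemblies
# that the whole-chromosome caller cannot compare directly.

#' Select the best HSP per (gene, pair)
#'
#' Keeps the HSP with the largest aligned length; ties broken by higher
#' bitscore, then higher identity. \code{contains_n} is set when the aligned
#' query or subject sequence carries any N.
#'
#' @param hsps data frame in [read_blast_tab()] layout; rows are HSPs for one
#'   or more (qseqid, sseqid) gene/pair combinations.
#' @return one row per (qseqid, sseqid): \code{gene_id}, \code{subject},
#'   \code{identity_pct}, \code{hsp_length}, \code{contains_n}.
#' @export
select_best_hsp <- function(hsps) {
  if (nrow(hsps) == 0L)
    return(data.frame(gene_id = character(0), subject = character(0),
                      identity_pct = numeric(0), hsp_length = numeric(0),
                      contains_n = logical(0), stringsAsFactors = FALSE))
  key <- paste(hsps$qseqid, hsps$sseqid, sep = "\r")
  ord <- order(key, -hsps$length, -hsps$bitscore, -hsps$pident)
  h <- hsps[ord, , drop = FALSE]
  first <- !duplicated(key[ord])
  h <- h[first, , drop = FALSE]
  data.frame(gene_id = h$qseqid, subject = h$sseqid,
             identity_pct = h$pident, hsp_length = h$length,
             contains_n = (h$qNs + h$sNs) > 0, stringsAsFactors = FALSE)
}

#' Filter gene alignments by projection consistency and N content
#'
#' Drops (a) genes whose projection is not on the expected chromosome, (b)
#' genes with more than one projection on the expected chromosome, and (c)
#' alignments whose aligned sequence contains Ns.
#'
#' @param gas best-HSP table from [select_best_hsp()].
#' @param projections [gene_projections()] table for the assembly being
#'   aligned (one assembly).
#' @param expected_chrom chromosome the genes must project to.
#' @return the surviving alignments with a \code{ref_rank} column joined from
#'   the projections, sorted by rank.
#' @export
filter_gene_alignments <- function(gas, projections, expected_chrom) {
  pr <- projections[projections$chrom == expected_chrom, , drop = FALSE]
  dup <- unique(pr$gene_id[duplicated(pr$gene_id)])
  pr <- pr[!pr$gene_id %in% dup, , drop = FALSE]
  keep <- gas$gene_id %in% pr$gene_id & !gas$contains_n
  out <- gas[keep, , drop = FALSE]
  out$ref_rank <- pr$ref_rank[match(out$gene_id, pr$gene_id)]
  out <- out[order(out$ref_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sliding-window identical-by-state scan over gene alignments
#'
#' Windows of \code{W} consecutive surviving genes advance one gene at a time
#' (consecutive means consecutive among survivors of the filters, which bridges
#' N-removed genes). In each window the \code{ceiling(trim_frac * W)}
#' lowest-identity alignments are removed (3 of 25 at the defaults) and the
#' window is identical-by-state iff the mean of the remainder equals 100%
#' (within 1e-9; identities derive from integer mismatch counts, so exactness
#' is well defined). Partial windows are not emitted.
#'
#' @param gas filtered table from [filter_gene_alignments()], sorted by
#'   \code{ref_rank}.
#' @param W window size in genes (default 25).
#' @param trim_frac fraction of lowest-identity alignments removed per window
#'   (default 0.10).
#' @return data frame of window calls: \code{start_rank}, \code{end_rank}
#'   (ref_rank of terminal genes), \code{start_idx}, \code{end_idx} (indices in
#'   the surviving-gene order), \code{trimmed_mean}, \code{identical}.
#' @export
window_scan <- function(gas, W = 25, trim_frac = 0.10) {
  empty <- data.frame(start_rank = integer(0), end_rank = integer(0),
                      start_idx = integer(0), end_idx = integer(0),
                      trimmed_mean = numeric(0), identical = logical(0))
  n <- nrow(gas)
  if (n < W) {
    warning("fewer than W = ", W, " genes; no windows emitted")
    return(empty)
  }
  if (is.unsorted(gas$ref_rank)) stop("gas must be sorted by ref_rank")
  n_trim <- ceiling(trim_frac * W)
  starts <- seq_len(n - W + 1L)
  tm <- vapply(starts, function(s) {
    ids <- sort(gas$identity_pct[s:(s + W - 1L)])
    mean(ids[(n_trim + 1L):W])
  }, numeric(1))
  data.frame(start_rank = gas$ref_rank[starts],
             end_rank = gas$ref_rank[starts + W - 1L],
             start_idx = starts, end_idx = starts + W - 1L,
             trimmed_mean = tm,
             identical = tm >= 100 - .IDENTITY_EPS)
}

#' Merge identical windows into blocks and lift to assembly coordinates
#'
#' Overlapping or adjacent identical-by-state windows are merged into maximal
#' runs over the surviving-gene order; each run spans from the full extent of
#' its first gene to the full extent of its last gene in the reference
#' annotation, then is lifted into the target assembly with [lift_interval()]
#' (identity when \code{target_assembly} equals the annotation's assembly).
#'
#' @param calls window table from [window_scan()].
#' @param gas the filtered gene alignments the windows were computed over.
#' @param projections [gene_projections()] table covering the reference
#'   annotation assembly and the target assembly.
#' @param ref_assembly assembly name of the reference annotation.
#' @param target_assembly assembly whose coordinates the blocks are reported
#'   in.
#' @param chrom chromosome id in the reference annotation.
#' @param ref_cultivar,query_cultivar labels stamped on the blocks.
#' @param gap,min_run lift parameters, see [lift_interval()].
#' @return a [haplotype_blocks()] table with source \code{"blast"}.
#' @export
windows_to_blocks <- function(calls, gas, projections, ref_assembly,
                              target_assembly, chrom,
                              ref_cultivar = "ref", query_cultivar = "query",
                              gap = 20, min_run = 10) {
  id <- calls[calls$identical, , drop = FALSE]
  if (nrow(id) == 0L) return(empty_blocks())
  ord <- order(id$start_idx)
  id <- id[ord, , drop = FALSE]
  # windows step by one gene: runs of identical windows with start_idx gaps <= 1
  brk <- c(0L, which(diff(id$start_idx) > 1L), nrow(id))
  ref_pr <- projections[projections$assembly == ref_assembly &
                          projections$chrom == chrom, , drop = FALSE]
  out <- empty_blocks()
  for (k in seq_len(length(brk) - 1L)) {
    i <- (brk[k] + 1L):brk[k + 1L]
    first_gene <- gas$gene_id[min(id$start_idx[i])]
    last_gene <- gas$gene_id[max(id$end_idx[i])]
    span <- range(ref_pr$start[ref_pr$gene_id %in% c(first_gene, last_gene)],
                  ref_pr$end[ref_pr$gene_id %in% c(first_gene, last_gene)])
    if (target_assembly == ref_assembly) {
      runs <- data.frame(chrom = chrom, start = span[1], end = span[2])
    } else {
      res <- lift_interval(list(chrom = chrom, start = span[1], end = span[2]),
                           ref_assembly, target_assembly, projections,
                           gap, min_run)
      if (res$status == "failed") {
        warning("lift failed for gene-window block ", span[1], "-", span[2],
                "; dropped")
        next
      }
      runs <- res$runs
    }
    out <- rbind(out, haplotype_blocks(ref_cultivar, query_cultivar,
                                       runs$chrom, runs$start, runs$end,
                                       source = "blast"))
  }
  rownames(out) <- NULL
  out
}

#' Combine binned-caller and gene-window blocks
#'
#' The final call set keeps every binned-caller block plus every gene-window
#' block that is not redundant, where redundant means overlapping (>= 1 bp)
#' some binned block while being shorter than the bin size.
#'
#' @param nucmer,blast block tables for the same pair and chromosome.
#' @param bin_size bin width of the binned caller in bp.
#' @return combined [haplotype_blocks()] table; each surviving block keeps its
#'   original source tag.
#' @export
combine_blocks <- function(nucmer, blast, bin_size = 5e6) {
  if (nrow(blast) == 0L) return(nucmer)
  if (nrow(nucmer) == 0L) return(blast)
  bl <- IRanges::IRanges(blast$start, blast$end)
  nu <- IRanges::IRanges(nucmer$start, nucmer$end)
  overlaps <- IRanges::overlapsAny(bl, nu)
  short <- (blast$end - blast$start + 1) < bin_size
  keep <- !(overlaps & short)
  out <- rbind(nucmer, blast[keep, , drop = FALSE])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision, recall and F1 of gene-window blocks against binned blocks
#'
#' Precision = gene-window blocks overlapping (>= 1 bp) at least one binned
#' block / total gene-window blocks; recall = binned blocks overlapping at
#' least one gene-window block / total binned blocks;
#' F1 = 2PR/(P+R) (0 when P + R = 0). An empty candidate or truth set makes
#' the corresponding score 0, flagged in the result.
#'
#' @param blast_blocks,nucmer_blocks block tables for the same pair/chromosome.
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{undefined} (character vector naming empty sides, if any).
#' @export
precision_recall_f1 <- function(blast_blocks, nucmer_blocks) {
  undefined <- character(0)
  if (nrow(blast_blocks) == 0L) undefined <- c(undefined, "precision")
  if (nrow(nucmer_blocks) == 0L) undefined <- c(undefined, "recall")
  if (length(undefined)) {
    p <- if (nrow(blast_blocks)) NA else 0
    r <- if (nrow(nucmer_blocks)) NA else 0
    if (is.na(p)) p <- 0
    if (is.na(r)) r <- 0
    return(list(precision = p, recall = r, f1 = 0, undefined = undefined))
  }
  bl <- IRanges::IRanges(blast_blocks$start, blast_blocks$end)
  nu <- IRanges::IRanges(nucmer_blocks$start, nucmer_blocks$end)
  p <- sum(IRanges::overlapsAny(bl, nu)) / length(bl)
  r <- sum(IRanges::overlapsAny(nu, bl)) / length(nu)
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1, undefined = undefined)
}

#' Precision/recall sweep over window size and flank configurations
#'
#' Runs [window_scan()] + [windows_to_blocks()] for each supplied alignment
#' set and scores it against the binned-caller blocks, reproducing the
#' parameter-selection analysis (window sizes 10-30 genes, flanks CDS/0/1/2/5
#' kb in the published design).
#'
#' @param gas_by_config named list of filtered gene-alignment tables; names
#'   are configuration labels. Each element must carry attributes \code{"W"}
#'   (window size) or the \code{W} column default is used.
#' @param nucmer_blocks truth blocks from the binned caller.
#' @param configs data frame with columns \code{label}, \code{W},
#'   \code{flank} describing each element of \code{gas_by_config}.
#' @param projections,ref_assembly,chrom passed to [windows_to_blocks()].
#' @param trim_frac trim fraction per window (default 0.10).
#' @return \code{configs} with appended \code{precision}, \code{recall},
#'   \code{f1} columns, and attribute \code{"best"} naming the max-F1 row.
#' @export
parameter_sweep <- function(gas_by_config, nucmer_blocks, configs,
                            projections, ref_assembly, chrom,
                            trim_frac = 0.10) {
  stopifnot(all(configs$label %in% names(gas_by_config)))
  res <- configs
  res$precision <- NA_real_; res$recall <- NA_real_; res$f1 <- NA_real_
  for (i in seq_len(nrow(configs))) {
    gas <- gas_by_config[[configs$label[i]]]
    calls <- suppressWarnings(window_scan(gas, W = configs$W[i],
                                          trim_frac = trim_frac))
    blocks <- windows_to_blocks(calls, gas, projections, ref_assembly,
                                ref_assembly, chrom)
    pr <- precision_recall_f1(blocks, nucmer_blocks)
    res$precision[i] <- pr$precision
    res$recall[i] <- pr$recall
    res$f1[i] <- pr$f1
  }
  attr(res, "best") <- res$label[which.max(res$f1)]
  res
}
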