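# Gene-anchored interval conversion between assemblies. Shared gene
# projections are the only anchors: genes inside the source interval are
# located in the target assembly, ordered by target position, joined into runs
# tolerating rank gaps, and each run reported by its first and last target
# coordinate. No base-level chain liftover is attempted.

#' Lift an interval from one assembly to another via gene anchors
#'
#' Algorithm: (1) collect genes whose projection in \code{source} lies within
#' the interval; (2) find their projections in \code{target} (genes projected
#' more than once in the target are excluded as ambiguous anchors); (3) sort by
#' target position; (4) join consecutive genes into runs wherever the gap in
#' the target's chromosome-wide projected-gene rank is at most \code{gap}
#' intervening genes; (5) if at least one run holds \code{min_run} genes, keep
#' all such runs (status \code{"full"}), otherwise keep only the longest run
#' (status \code{"longest_only"}); (6) report each run as the span from its
#' first to its last target coordinate.
#'
#' @param interval list or vector with \code{chrom}, \code{start}, \code{end}
#'   in source coordinates (1-based inclusive).
#' @param source,target assembly names present in \code{projections}.
#' @param projections table from [gene_projections()] covering both assemblies;
#'   gene ids are the cross-assembly join key.
#' @param gap maximum number of intervening target genes bridged within a run
#'   (default 20).
#' @param min_run minimum genes per reported run (default 10).
#' @return a list of class \code{"lift_result"} with \code{runs} (data frame:
#'   \code{chrom}, \code{start}, \code{end}, \code{n_genes}) and \code{status}
#'   in \code{\{"full", "longest_only", "failed"\}}.
#' @export
lift_interval <- function(interval, source, target, projections, gap = 20,
                          min_run = 10) {
  if (is.list(interval))
    interval <- c(chrom = interval$chrom, start = interval$start,
                  end = interval$end)
  chrom <- as.character(interval[["chrom"]])
  start <- as.numeric(interval[["start"]]); end <- as.numeric(interval[["end"]])
  fail <- structure(list(runs = data.frame(chrom = character(0),
                                           start = numeric(0), end = numeric(0),
                                           n_genes = integer(0)),
                         status = "failed"), class = "lift_result")
  src <- projections[projections$assembly == source &
                       projections$chrom == chrom &
                       projections$start >= start & projections$end <= end, ,
                     drop = FALSE]
  if (nrow(src) == 0L) return(fail)
  tgt_all <- projections[projections$assembly == target, , drop = FALSE]
  # ambiguous anchors: multiply projected genes in the target
  dup <- unique(tgt_all$gene_id[duplicated(tgt_all$gene_id)])
  tgt_all <- tgt_all[!tgt_all$gene_id %in% dup, , drop = FALSE]
  if (nrow(tgt_all) == 0L) return(fail)
  # chromosome-wide target gene rank (per target chromosome, by position)
  tgt_all$.rank <- NA_integer_
  for (ch in unique(tgt_all$chrom)) {
    i <- which(tgt_all$chrom == ch)
    tgt_all$.rank[i] <- rank(tgt_all$start[i], ties.method = "first")
  }
  tgt <- tgt_all[tgt_all$gene_id %in% src$gene_id, , drop = FALSE]
  if (nrow(tgt) == 0L) return(fail)
  runs <- list()
  for (ch in unique(tgt$chrom)) {
    t <- tgt[tgt$chrom == ch, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    gaps <- diff(t$.rank) - 1L
    brk <- c(0L, which(gaps > gap), nrow(t))
    for (k in seq_len(length(brk) - 1L)) {
      i <- (brk[k] + 1L):brk[k + 1L]
      runs[[length(runs) + 1L]] <- data.frame(
        chrom = ch, start = min(t$start[i]), end = max(t$end[i]),
        n_genes = length(i), stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  if (any(runs$n_genes >= min_run)) {
    runs <- runs[runs$n_genes >= min_run, , drop = FALSE]
    status <- "full"
  } else {
    runs <- runs[which.max(runs$n_genes), , drop = FALSE]
    status <- "longest_only"
  }
  runs <- runs[order(runs$chrom, runs$start), , drop = FALSE]
  rownames(runs) <- NULL
  structure(list(runs = runs, status = status), class = "lift_result")
}

#' @export
print.lift_result <- function(x, ...) {
  cat("lift_result (", x$status, "): ", nrow(x$runs), " run(s)\n", sep = "")
  if (nrow(x$runs)) print(x$runs)
  invisible(x)
}

#' Build an interval lifter closure for [reciprocal_consistency()]
#'
#' @inheritParams lift_interval
#' @param chrom chromosome the intervals live on in the source assembly.
#' @return a function mapping \code{c(start, end)} to the spanning
#'   \code{c(start, end)} of the lifted runs, or NULL on failure.
#' @export
make_gene_lifter <- function(source, target, projections, chrom, gap = 20,
                             min_run = 10) {
  force(projections)
  function(interval) {
    res <- lift_interval(list(chrom = chrom, start = interval[1],
                              end = interval[2]),
                         source, target, projections, gap, min_run)
    if (res$status == "failed" || nrow(res$runs) == 0L) return(NULL)
    c(min(res$runs$start), max(res$runs$end))
  }
}
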