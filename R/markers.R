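# Haplotype-group profiles over a minimum haplotype block (MHB), germplasm
# assignment by marker-profile matching, marker panel design, and platform
# resolution reports. The MHB is the interval across which no recombination
# breakpoints between haplotype groups were observed; marker profiles over it
# define the groups.

#' Restrict a genotype matrix to markers inside an interval
#'
#' @param gm a [genotype_matrix()].
#' @param chrom,start,end the minimum haplotype block interval (bp, 1-based
#'   inclusive).
#' @return the restricted [genotype_matrix()].
#' @export
restrict_to_interval <- function(gm, chrom, start, end) {
  keep <- gm$markers$chrom == chrom & gm$markers$pos >= start &
    gm$markers$pos <= end
  genotype_matrix(gm$calls[, keep, drop = FALSE],
                  gm$markers[keep, , drop = FALSE])
}

#' Width of a minimum haplotype block in Mbp
#' @param start,end interval bounds in bp (or Mbp if already scaled).
#' @param unit divisor applied to \code{end - start} (default 1e6: bp in, Mbp
#'   out; use 1 when the bounds are already in Mbp).
#' @return \code{(end - start) / unit}.
#' @export
mhb_span_mbp <- function(start, end, unit = 1e6) (end - start) / unit

#' Build haplotype-group allele profiles from exemplar lines
#'
#' Each group's profile is the marker-allele vector of its exemplar line(s)
#' over the matrix. Markers whose calls are inconsistent among replicate
#' exemplars of the same group are excluded from all profiles. Groups whose
#' profiles coincide over the surviving markers are merged into one
#' resolvability class labelled by joining the group names with "/".
#'
#' @param gm a [genotype_matrix()] restricted to the MHB.
#' @param exemplar_lines named list, group id -> character vector of exemplar
#'   line ids (several ids = replicates).
#' @return object of class \code{"haplotype_profiles"}: list with
#'   \code{profiles} (group x marker matrix, possibly with merged row names),
#'   \code{markers} (surviving marker table), \code{dropped_markers}.
#' @export
build_group_profiles <- function(gm, exemplar_lines) {
  stopifnot(length(exemplar_lines) >= 1)
  miss <- setdiff(unlist(exemplar_lines), rownames(gm$calls))
  if (length(miss)) stop("exemplar lines absent from matrix: ",
                         paste(miss, collapse = ", "))
  groups <- names(exemplar_lines)
  prof <- matrix(NA_real_, nrow = length(groups), ncol = ncol(gm$calls),
                 dimnames = list(groups, colnames(gm$calls)))
  inconsistent <- rep(FALSE, ncol(gm$calls))
  for (g in groups) {
    calls <- gm$calls[exemplar_lines[[g]], , drop = FALSE]
    if (anyNA(calls)) {
      bad <- colnames(calls)[apply(is.na(calls), 2, any)]
      stop("exemplar(s) for group ", g, " have missing calls at: ",
           paste(bad, collapse = ", "))
    }
    rep_consistent <- apply(calls, 2, function(v) length(unique(v)) == 1L)
    inconsistent <- inconsistent | !rep_consistent
    prof[g, ] <- calls[1, ]
  }
  keep <- !inconsistent
  prof <- prof[, keep, drop = FALSE]
  markers <- gm$markers[keep, , drop = FALSE]
  # merge groups indistinguishable over the surviving markers
  key <- apply(prof, 1, paste, collapse = ",")
  merged <- lapply(split(groups, key), identity)
  labels <- vapply(merged, function(gs) paste(sort(gs), collapse = "/"),
                   character(1))
  mp <- prof[vapply(merged, `[`, character(1), 1), , drop = FALSE]
  rownames(mp) <- labels
  mp <- mp[order(rownames(mp)), , drop = FALSE]
  structure(list(profiles = mp, markers = markers,
                 dropped_markers = gm$markers$marker_id[inconsistent]),
            class = "haplotype_profiles")
}

#' @export
print.haplotype_profiles <- function(x, ...) {
  cat("haplotype_profiles:", nrow(x$profiles), "group(s) x",
      ncol(x$profiles), "marker(s)\n")
  if (length(x$dropped_markers))
    cat("  dropped (inconsistent replicates):",
        paste(x$dropped_markers, collapse = ", "), "\n")
  invisible(x)
}

#' Assign genotyped lines to haplotype groups by profile matching
#'
#' A line matches a profile when its non-missing calls agree at every shared
#' marker. Exactly one match gives that group's label; several matches give a
#' merged label joining the candidate groups with "/"; no match gives a novel
#' label ("N1", "N2", ... by order of first appearance, identical novel
#' vectors sharing a label); lines with call rate below \code{min_callrate}
#' are "unassigned".
#'
#' @param gm a [genotype_matrix()] over (a subset of) the profile markers.
#' @param profiles a [build_group_profiles()] result.
#' @param min_callrate minimum fraction of profile markers called (default
#'   0.8).
#' @return named character vector, line id -> label.
#' @export
assign_lines <- function(gm, profiles, min_callrate = 0.8) {
  common <- intersect(colnames(profiles$profiles), colnames(gm$calls))
  if (length(common) == 0L) stop("no markers shared with the profiles")
  prof <- profiles$profiles[, common, drop = FALSE]
  calls <- gm$calls[, common, drop = FALSE]
  labels <- character(nrow(calls))
  names(labels) <- rownames(calls)
  novel <- list()
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    ok <- !is.na(v)
    if (mean(ok) < min_callrate) {
      labels[i] <- "unassigned"
      next
    }
    hits <- apply(prof, 1, function(p) all(p[ok] == v[ok]))
    if (sum(hits) == 1L) {
      labels[i] <- rownames(prof)[hits]
    } else if (sum(hits) > 1L) {
      labels[i] <- paste(sort(rownames(prof)[hits]), collapse = "/")
    } else {
      key <- paste(ifelse(ok, v, "."), collapse = ",")
      if (is.null(novel[[key]])) novel[[key]] <- paste0("N", length(novel) + 1L)
      labels[i] <- novel[[key]]
    }
  }
  labels
}

#' Design a haplotype-informed marker panel
#'
#' Greedy max-min selection: starting empty, repeatedly add the candidate
#' marker that most increases the minimum pairwise Hamming distance between
#' group profiles; ties are broken by the marker that most reduces the largest
#' positional gap between selected markers (favouring an even spread across
#' the MHB), then by position order. Selection stops once every pair differs
#' at \code{min_diff} or more selected markers.
#'
#' @param profiles a [build_group_profiles()] result over the candidate
#'   markers (groups must be pairwise distinct over the candidates).
#' @param min_diff required minimum pairwise profile differences (default 3,
#'   giving redundancy against single assay failures).
#' @param interval optional \code{c(start, end)} of the MHB used for the gap
#'   criterion; defaults to the candidate marker span.
#' @return object of class \code{"panel_design"}: \code{markers} (selected
#'   marker table), \code{pairwise_diff} (group x group matrix over the
#'   panel), \code{min_pairwise_diff}, \code{max_gap} (largest inter-marker
#'   gap in bp, interval ends included).
#' @export
design_panel <- function(profiles, min_diff = 3, interval = NULL) {
  prof <- profiles$profiles
  mk <- profiles$markers
  G <- nrow(prof)
  if (G < 2) stop("need at least two haplotype groups")
  pairs <- utils::combn(G, 2)
  # per-candidate indicator of which pairs it separates
  sep <- apply(prof, 2, function(col) col[pairs[1, ]] != col[pairs[2, ]])
  sep <- matrix(sep, ncol = ncol(prof))  # pairs x markers
  full <- rowSums(sep)
  if (any(full < min_diff)) {
    i <- which(full < min_diff)[1]
    stop("infeasible: groups ", rownames(prof)[pairs[1, i]], " and ",
         rownames(prof)[pairs[2, i]], " differ at only ", full[i],
         " candidate marker(s); min_diff = ", min_diff)
  }
  if (is.null(interval)) interval <- range(mk$pos)
  selected <- integer(0)
  count <- rep(0, ncol(pairs))  # per-pair differences among selected
  max_gap <- function(sel) {
    pos <- sort(c(interval, mk$pos[sel]))
    max(diff(pos))
  }
  while (min(count) < min_diff) {
    remaining <- setdiff(seq_len(ncol(prof)), selected)
    deficient <- count < min_diff
    # primary: new capped minimum pairwise distance; secondary: how many
    # still-deficient pairs the marker separates (drives termination)
    gain <- vapply(remaining, function(j) {
      min(pmin(count + sep[, j], min_diff)) * (ncol(pairs) + 1) +
        sum(sep[deficient, j])
    }, numeric(1))
    best <- remaining[gain == max(gain)]
    if (length(best) > 1L) {
      gaps <- vapply(best, function(j) max_gap(c(selected, j)), numeric(1))
      best <- best[gaps == min(gaps)]
      best <- best[order(mk$pos[best])]
    }
    j <- best[1]
    selected <- c(selected, j)
    count <- count + sep[, j]
  }
  selected <- sort(selected)
  panel <- prof[, selected, drop = FALSE]
  d <- matrix(0, G, G, dimnames = list(rownames(prof), rownames(prof)))
  for (k in seq_len(ncol(pairs)))
    d[pairs[1, k], pairs[2, k]] <- d[pairs[2, k], pairs[1, k]] <-
      sum(panel[pairs[1, k], ] != panel[pairs[2, k], ])
  structure(list(markers = mk[selected, , drop = FALSE],
                 pairwise_diff = d,
                 min_pairwise_diff = min(d[upper.tri(d)]),
                 max_gap = max_gap(selected),
                 profiles = panel),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat("panel_design:", nrow(x$markers), "markers, min pairwise diff",
      x$min_pairwise_diff, ", max positional gap",
      format(x$max_gap, big.mark = ","), "bp\n")
  invisible(x)
}

#' Distinguishable haplotype-group partitions per genotyping platform
#'
#' For each platform's profile set, groups are partitioned into
#' indistinguishability classes (identical allele vectors over that platform's
#' markers) — e.g. a genic array may collapse H1 and H2 into one class.
#'
#' @param profiles_by_platform named list of [build_group_profiles()] results
#'   (or plain group x marker matrices).
#' @return data frame with \code{platform}, \code{classes} (string like
#'   "H1/H2 | H3 | H4"), \code{n_classes}.
#' @export
resolution_report <- function(profiles_by_platform) {
  rows <- lapply(names(profiles_by_platform), function(pl) {
    p <- profiles_by_platform[[pl]]
    if (inherits(p, "haplotype_profiles")) p <- p$profiles
    key <- apply(p, 1, paste, collapse = ",")
    classes <- vapply(split(rownames(p), key),
                      function(gs) paste(sort(gs), collapse = "/"),
                      character(1))
    classes <- sort(unname(classes))
    data.frame(platform = pl, classes = paste(classes, collapse = " | "),
               n_classes = length(classes), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
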