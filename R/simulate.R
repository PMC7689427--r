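# Seeded synthetic pangenome generator. An ancestral chromosome is shared by
# all cultivars; planted blocks are segments where a set of cultivars carries
# one common haplotype (identical-by-descent, hence pairwise identical);
# outside them each cultivar accumulates private substitutions at the
# near-identical background rate (default 3.2e-4 per site pairwise, the
# ~10,000-year divergence level); introgression-like segments add 0.5-1%
# divergence; N runs interrupt alignments. Substitutions are i.i.d. per site
# with no indels; alignment records are emitted by construction (collinear
# segments broken at N runs, with exact mismatch counts), so callers can be
# scored against planted truth without running an aligner.
#
# All randomness flows from the single spec seed in a fixed draw order, so a
# spec is a reproducible study condition, not a stream of surprises.

# ---- interval helpers (closed integer intervals as 2-column matrices) ----

.iv <- function(start, end) {
  m <- cbind(as.numeric(start), as.numeric(end))
  m[m[, 1] <= m[, 2], , drop = FALSE]
}

.iv_union <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2] + 1) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else out <- rbind(out, m[i, ])
  }
  out
}

.iv_subtract <- function(a, b) {
  # a minus union(b)
  b <- .iv_union(b)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1]; e <- a[i, 2]
    cur <- s
    for (j in seq_len(nrow(b))) {
      if (b[j, 2] < cur || b[j, 1] > e) next
      if (b[j, 1] > cur) out <- rbind(out, c(cur, b[j, 1] - 1))
      cur <- max(cur, b[j, 2] + 1)
      if (cur > e) break
    }
    if (cur <= e) out <- rbind(out, c(cur, e))
  }
  if (is.null(out)) .iv(numeric(0), numeric(0)) else out
}

.iv_width <- function(m) if (nrow(m) == 0L) 0 else sum(m[, 2] - m[, 1] + 1)

.sample_in_intervals <- function(n, iv) {
  w <- .iv_width(iv)
  n <- min(n, w)
  if (n == 0L) return(numeric(0))
  widths <- iv[, 2] - iv[, 1] + 1
  cum <- cumsum(widths)
  offs <- sort(sample.int(w, n))          # offsets in 1..w
  k <- findInterval(offs - 0.5, cum) + 1L # interval holding each offset
  start_off <- c(0, cum[-length(cum)])
  iv[k, 1] + (offs - start_off[k] - 1)
}

# ---- spec -----------------------------------------------------------------

#' Specify a synthetic pangenome
#'
#' The defaults describe the study condition the caller is validated under:
#' a 50-Mbp chromosome shared by three cultivars, one planted 20-Mbp
#' identical-by-descent block between the first two, near-identical
#' background divergence of 3.2e-4 (two lineages at 1.6e-8 substitutions
#' nt^-1 yr^-1 for 10,000 years), one 0.7% introgression-like segment in the
#' third cultivar, and N runs interrupting the planted block.
#'
#' @param n_cultivars number of cultivars (named \code{cv1}, \code{cv2}, ...).
#' @param chrom chromosome id used in every emitted file.
#' @param chrom_len chromosome length in bp.
#' @param planted_blocks data frame with \code{cultivars}
#'   (";"-separated member names), \code{start}, \code{end}: segments where
#'   the members carry one shared haplotype.
#' @param background_divergence pairwise substitution probability per site
#'   outside planted blocks (default 3.2e-4).
#' @param introgressions data frame \code{cultivar}, \code{start}, \code{end},
#'   \code{divergence} of wild-relative-like segments (default divergence
#'   0.007).
#' @param n_runs data frame \code{cultivar}, \code{start}, \code{length} of
#'   N runs.
#' @param gene_density genes per Mbp laid on a regular grid shared by all
#'   assemblies (default 20).
#' @param gene_length gene body length in bp (default 3000).
#' @param genic_conservation when TRUE (default) background/haplotype
#'   substitutions are placed outside gene bodies (genic sequence is far more
#'   conserved than intergenic in wheat), which is what makes flankless
#'   gene alignments blind to near-identical divergence.
#' @param marker_density genotyping markers per Mbp (default 2).
#' @param noise_alignments short (< 20 kb) alignment records emitted per pair
#'   so length filtering is exercised (default 3).
#' @param aln_chunk target alignment-record length in bp (default 1e5).
#'   Real whole-chromosome aligners emit many records per chromosome, not
#'   one; emitted segments are additionally cut at N runs and at planted
#'   block/introgression boundaries, where alignment structure changes.
#' @param seed mandatory RNG seed.
#' @return object of class \code{"pangenome_spec"}.
#' @export
pangenome_spec <- function(n_cultivars = 3,
                           chrom = "chr1A",
                           chrom_len = 5e7,
                           planted_blocks = data.frame(
                             cultivars = "cv1;cv2", start = 15e6, end = 35e6),
                           background_divergence = 3.2e-4,
                           introgressions = data.frame(
                             cultivar = "cv3", start = 5e6, end = 10e6,
                             divergence = 0.007),
                           n_runs = data.frame(
                             cultivar = c("cv1", "cv2"),
                             start = c(22e6, 45e6), length = c(30e3, 10e3)),
                           gene_density = 20,
                           gene_length = 3000,
                           genic_conservation = TRUE,
                           marker_density = 2,
                           noise_alignments = 3,
                           aln_chunk = 1e5,
                           seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  cultivars <- paste0("cv", seq_len(n_cultivars))
  pb <- planted_blocks
  if (!is.null(pb) && nrow(pb)) {
    pb$members <- strsplit(as.character(pb$cultivars), ";", fixed = TRUE)
    bad <- setdiff(unlist(pb$members), cultivars)
    if (length(bad)) stop("unknown cultivar(s) in planted blocks: ",
                          paste(bad, collapse = ", "))
    if (any(pb$start < 1) || any(pb$end > chrom_len))
      stop("planted block outside chromosome")
    if (nrow(pb) > 1) {
      iv <- .iv(pb$start, pb$end)
      if (nrow(.iv_union(iv)) < nrow(iv))
        stop("overlapping planted blocks are contradictory")
    }
  }
  if (!is.null(introgressions) && nrow(introgressions) && !is.null(pb) &&
      nrow(pb)) {
    for (i in seq_len(nrow(introgressions))) {
      for (j in seq_len(nrow(pb))) {
        if (introgressions$cultivar[i] %in% pb$members[[j]] &&
            introgressions$start[i] <= pb$end[j] &&
            introgressions$end[i] >= pb$start[j])
          stop("introgression in ", introgressions$cultivar[i],
               " contradicts a planted block it belongs to")
      }
    }
  }
  stopifnot(background_divergence >= 0, background_divergence < 1)
  structure(list(n_cultivars = n_cultivars, cultivars = cultivars,
                 chrom = chrom, chrom_len = chrom_len, planted_blocks = pb,
                 background_divergence = background_divergence,
                 introgressions = introgressions, n_runs = n_runs,
                 gene_density = gene_density, gene_length = gene_length,
                 genic_conservation = genic_conservation,
                 marker_density = marker_density,
                 noise_alignments = noise_alignments, aln_chunk = aln_chunk,
                 seed = seed),
            class = "pangenome_spec")
}

#' @export
print.pangenome_spec <- function(x, ...) {
  cat("pangenome_spec:", x$n_cultivars, "cultivars,",
      format(x$chrom_len, big.mark = ","), "bp", x$chrom, "\n")
  cat("  planted blocks:", if (is.null(x$planted_blocks)) 0 else
    nrow(x$planted_blocks),
    "| background divergence:", x$background_divergence,
    "| seed:", x$seed, "\n")
  invisible(x)
}

#' Mean and 95% interval of mismatch counts under binomial substitution
#'
#' Calibration helper: over \code{length} sites at per-site divergence
#' \code{divergence}, mismatches are Binomial(length, divergence); returns the
#' mean and a normal-approximation 95% interval.
#'
#' @param divergence per-site substitution probability.
#' @param length number of sites.
#' @return list \code{mean}, \code{lower}, \code{upper}.
#' @export
expected_mismatches <- function(divergence, length) {
  m <- divergence * length
  sd <- sqrt(length * divergence * (1 - divergence))
  list(mean = m, lower = max(0, m - 1.96 * sd), upper = m + 1.96 * sd)
}

# ---- generator ------------------------------------------------------------

.gene_grid <- function(spec) {
  n_genes <- max(0L, floor(spec$chrom_len / 1e6 * spec$gene_density))
  if (n_genes == 0L)
    return(data.frame(gene_id = character(0), start = numeric(0),
                      end = numeric(0)))
  spacing <- spec$chrom_len / n_genes
  start <- floor((seq_len(n_genes) - 0.5) * spacing) + 1
  end <- pmin(start + spec$gene_length - 1, spec$chrom_len)
  data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Simulate a synthetic pangenome
#'
#' Generates, from one seed, everything the pipeline consumes: pairwise
#' alignment records with exact mismatch counts, gene projections for every
#' cultivar, SNP records against the first cultivar, a genotype matrix, and
#' the planted-block ground truth. Chromosome sequences are materialised only
#' when \code{emit_sequences = TRUE} (needed for FASTA output and SNP flank
#' extraction); all other outputs derive from substitution maps and are cheap
#' at tens of megabases.
#'
#' @param spec a [pangenome_spec()].
#' @param emit_sequences also materialise per-cultivar chromosome sequences.
#' @return object of class \code{"pangenome_sim"} with elements
#'   \code{alignments} (named list per ordered pair "a|b"), \code{projections},
#'   \code{snps}, \code{genotypes}, \code{truth} (data frame of pairwise
#'   identical-by-state intervals), \code{groups} (cultivar -> haplotype
#'   group label), \code{sequences} (named character or NULL), \code{spec}.
#' @export
simulate_pangenome <- function(spec, emit_sequences = FALSE) {
  stopifnot(inherits(spec, "pangenome_spec"))
  set.seed(spec$seed)
  L <- spec$chrom_len
  cultivars <- spec$cultivars
  genes <- .gene_grid(spec)
  gene_iv <- .iv(genes$start, genes$end)
  half <- spec$background_divergence / 2

  anc <- NULL
  if (emit_sequences) anc <- sample.int(4L, L, replace = TRUE)

  pb <- spec$planted_blocks
  n_pb <- if (is.null(pb)) 0L else nrow(pb)
  hap_maps <- vector("list", n_pb)  # per planted block: pos + offset(1..3)
  for (j in seq_len(n_pb)) {
    region <- .iv(pb$start[j], pb$end[j])
    allowed <- if (spec$genic_conservation) .iv_subtract(region, gene_iv)
    else region
    m <- stats::rbinom(1, .iv_width(region), half)
    pos <- .sample_in_intervals(m, allowed)
    hap_maps[[j]] <- data.frame(pos = pos,
                                off = sample.int(3L, length(pos),
                                                 replace = TRUE))
  }

  # per-cultivar private substitutions outside its planted blocks
  priv <- vector("list", length(cultivars))
  names(priv) <- cultivars
  whole <- .iv(1, L)
  for (cv in cultivars) {
    own_blocks <- if (n_pb) .iv(pb$start[vapply(pb$members, function(m)
      cv %in% m, logical(1))], pb$end[vapply(pb$members, function(m)
        cv %in% m, logical(1))]) else .iv(numeric(0), numeric(0))
    region <- .iv_subtract(whole, own_blocks)
    allowed <- if (spec$genic_conservation) .iv_subtract(region, gene_iv)
    else region
    m <- stats::rbinom(1, .iv_width(region), half)
    pos <- .sample_in_intervals(m, allowed)
    priv[[cv]] <- data.frame(pos = pos,
                             off = sample.int(3L, length(pos), replace = TRUE))
  }

  # introgression-like segments: extra substitutions, genes included
  intro <- spec$introgressions
  if (!is.null(intro) && nrow(intro)) {
    for (i in seq_len(nrow(intro))) {
      cv <- intro$cultivar[i]
      region <- .iv(intro$start[i], intro$end[i])
      m <- stats::rbinom(1, .iv_width(region), intro$divergence[i])
      pos <- .sample_in_intervals(m, region)
      add <- data.frame(pos = pos,
                        off = sample.int(3L, length(pos), replace = TRUE))
      comb <- rbind(priv[[cv]], add)
      priv[[cv]] <- comb[!duplicated(comb$pos, fromLast = TRUE), , drop = FALSE]
    }
  }

  # full substitution map per cultivar (planted haplotypes shared verbatim)
  maps <- lapply(cultivars, function(cv) {
    parts <- list(priv[[cv]])
    for (j in seq_len(n_pb))
      if (cv %in% pb$members[[j]]) parts <- c(parts, list(hap_maps[[j]]))
    m <- do.call(rbind, parts)
    m[order(m$pos), , drop = FALSE]
  })
  names(maps) <- cultivars

  # N runs per cultivar
  nr <- spec$n_runs
  n_iv <- lapply(cultivars, function(cv) {
    if (is.null(nr) || !nrow(nr)) return(.iv(numeric(0), numeric(0)))
    r <- nr[nr$cultivar == cv, , drop = FALSE]
    .iv(r$start, pmin(r$start + r$length - 1, L))
  })
  names(n_iv) <- cultivars

  # pairwise alignment records: collinear segments broken at either N run
  pair_mismatch_pos <- function(a, b) {
    ma <- maps[[a]]; mb <- maps[[b]]
    ia <- match(ma$pos, mb$pos)
    shared_diff <- ma$pos[!is.na(ia) & ma$off != mb$off[ia]]
    only_a <- ma$pos[is.na(ia)]
    only_b <- mb$pos[!mb$pos %in% ma$pos]
    sort(c(shared_diff, only_a, only_b))
  }
  alignments <- list()
  truth_rows <- list()
  ordered_pairs <- expand.grid(a = cultivars, b = cultivars,
                               stringsAsFactors = FALSE)
  ordered_pairs <- ordered_pairs[ordered_pairs$a != ordered_pairs$b, ]
  ordered_pairs <- ordered_pairs[order(ordered_pairs$a, ordered_pairs$b), ]
  chunk_segments <- function(segs, cuts, chunk) {
    # split at biological boundaries, then into chunk-length records
    cuts <- sort(unique(cuts))
    out <- NULL
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, 1]; e <- segs[i, 2]
      inner <- cuts[cuts > s & cuts <= e]
      starts <- c(s, inner)
      ends <- c(inner - 1, e)
      for (j in seq_along(starts)) {
        st <- seq(starts[j], ends[j], by = chunk)
        en <- pmin(st + chunk - 1, ends[j])
        out <- rbind(out, cbind(st, en))
      }
    }
    out
  }
  for (r in seq_len(nrow(ordered_pairs))) {
    a <- ordered_pairs$a[r]; b <- ordered_pairs$b[r]
    segs <- .iv_subtract(whole, rbind(n_iv[[a]], n_iv[[b]]))
    cuts <- numeric(0)
    if (n_pb) cuts <- c(cuts, pb$start, pb$end + 1)
    if (!is.null(intro) && nrow(intro)) {
      ri <- intro[intro$cultivar %in% c(a, b), , drop = FALSE]
      cuts <- c(cuts, ri$start, ri$end + 1)
    }
    segs <- chunk_segments(segs, cuts, spec$aln_chunk)
    mpos <- pair_mismatch_pos(a, b)
    counts <- findInterval(segs[, 2], mpos) -
      findInterval(segs[, 1] - 1, mpos)
    rec <- alignment_records(
      ref_name = spec$chrom, query_name = spec$chrom,
      ref_start = segs[, 1], ref_end = segs[, 2],
      query_start = segs[, 1], query_end = segs[, 2],
      aln_length = segs[, 2] - segs[, 1] + 1, mismatches = counts)
    if (spec$noise_alignments > 0) {
      len <- sample(5000:15000, spec$noise_alignments, replace = TRUE)
      st <- sample.int(L - max(len), spec$noise_alignments)
      noise <- alignment_records(
        ref_name = spec$chrom, query_name = spec$chrom,
        ref_start = st, ref_end = st + len - 1,
        query_start = st, query_end = st + len - 1,
        aln_length = len,
        mismatches = stats::rbinom(spec$noise_alignments, len, 0.01))
      rec <- rbind(rec, noise)
    }
    alignments[[paste(a, b, sep = "|")]] <- rec
  }

  # truth: pairwise identical-by-state intervals from planted blocks
  for (j in seq_len(n_pb)) {
    mem <- pb$members[[j]]
    if (length(mem) < 2) next
    cmb <- utils::combn(sort(mem), 2)
    for (k in seq_len(ncol(cmb)))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        cultivar_a = cmb[1, k], cultivar_b = cmb[2, k], chrom = spec$chrom,
        start = pb$start[j], end = pb$end[j], stringsAsFactors = FALSE)
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(cultivar_a = character(0), cultivar_b = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0))

  # gene projections: identical grid in every assembly
  projections <- do.call(rbind, lapply(cultivars, function(cv)
    gene_projections(genes$gene_id, cv, spec$chrom, genes$start, genes$end)))

  # resolve ancestral alleles at all substituted positions
  all_pos <- sort(unique(unlist(lapply(maps, `[[`, "pos"))))
  anc_at <- if (!is.null(anc)) anc[all_pos] else
    sample.int(4L, length(all_pos), replace = TRUE)
  base_of <- function(map, positions) {
    # allele index (1..4) of a cultivar at given positions
    anc_idx <- anc_at[match(positions, all_pos)]
    hit <- match(positions, map$pos)
    off <- ifelse(is.na(hit), 0L, map$off[hit])
    ((anc_idx - 1L + off) %% 4L) + 1L
  }
  BASES <- c("A", "C", "G", "T")

  # SNP records: first cultivar as reference vs every other
  ref_cv <- cultivars[1]
  snp_list <- list()
  for (cv in cultivars[-1]) {
    mpos <- pair_mismatch_pos(ref_cv, cv)
    if (length(mpos) == 0L) next
    ref_al <- BASES[base_of(maps[[ref_cv]], mpos)]
    alt_al <- BASES[base_of(maps[[cv]], mpos)]
    in_n <- function(iv, p) {
      if (nrow(iv) == 0L) return(rep(FALSE, length(p)))
      Reduce(`|`, lapply(seq_len(nrow(iv)),
                         function(i) p >= iv[i, 1] & p <= iv[i, 2]))
    }
    ref_al[in_n(n_iv[[ref_cv]], mpos)] <- "N"
    alt_al[in_n(n_iv[[cv]], mpos)] <- "N"
    snp_list[[cv]] <- snp_records(spec$chrom, mpos, ref_al, alt_al, cv)
  }

  # genotype matrix: evenly spread markers over polymorphic positions
  snps_all <- collate_snps(snp_list)
  n_mk <- max(0L, floor(L / 1e6 * spec$marker_density))
  n_mk <- min(n_mk, nrow(snps_all))
  genotypes <- NULL
  if (n_mk >= 1L) {
    pick <- unique(round(seq(1, nrow(snps_all), length.out = n_mk)))
    mpos <- sort(snps_all$ref_pos[pick])
    markers <- data.frame(marker_id = sprintf("mk%05d", seq_along(mpos)),
                          chrom = spec$chrom, pos = mpos,
                          stringsAsFactors = FALSE)
    ref_base <- BASES[base_of(maps[[ref_cv]], mpos)]
    calls <- vapply(cultivars, function(cv) {
      al <- BASES[base_of(maps[[cv]], mpos)]
      v <- as.numeric(al != ref_base)
      iv <- n_iv[[cv]]
      for (i in seq_len(nrow(iv)))
        v[mpos >= iv[i, 1] & mpos <= iv[i, 2]] <- NA
      v
    }, numeric(length(mpos)))
    calls <- t(matrix(calls, nrow = length(mpos)))
    rownames(calls) <- cultivars
    colnames(calls) <- markers$marker_id
    genotypes <- genotype_matrix(calls, markers)
  }

  # haplotype-group labels: one group per distinct planted-block membership
  membership <- vapply(cultivars, function(cv)
    paste(vapply(seq_len(n_pb), function(j)
      cv %in% pb$members[[j]], logical(1)), collapse = ","), character(1))
  groups <- paste0("G", as.integer(factor(membership,
                                          levels = unique(membership))))
  names(groups) <- cultivars

  sequences <- NULL
  if (emit_sequences) {
    sequences <- vapply(cultivars, function(cv) {
      s <- anc
      m <- maps[[cv]]
      if (nrow(m)) {
        anc_idx <- anc[m$pos]
        s[m$pos] <- ((anc_idx - 1L + m$off) %% 4L) + 1L
      }
      chars <- BASES[s]
      iv <- n_iv[[cv]]
      for (i in seq_len(nrow(iv)))
        chars[iv[i, 1]:iv[i, 2]] <- "N"
      paste(chars, collapse = "")
    }, character(1))
  }

  structure(list(alignments = alignments, projections = projections,
                 snps = snp_list, genotypes = genotypes, truth = truth,
                 groups = groups, sequences = sequences, spec = spec,
                 subst_maps = maps, n_intervals = n_iv),
            class = "pangenome_sim")
}

#' @export
print.pangenome_sim <- function(x, ...) {
  cat("pangenome_sim:", length(x$spec$cultivars), "cultivars,",
      format(x$spec$chrom_len, big.mark = ","), "bp;",
      length(x$alignments), "ordered pairs;",
      nrow(x$truth), "truth interval(s)\n")
  invisible(x)
}

#' Per-gene alignment table for one ordered cultivar pair
#'
#' Emulates the gene +/- flank BLASTn route: for each gene on the shared
#' grid, the aligned span is the gene body extended by \code{flank} bp each
#' side (clipped to the chromosome), the mismatch count is the exact pairwise
#' count in the span, and N counts reflect each cultivar's N runs. One HSP
#' per gene, in [read_blast_tab()] column layout.
#'
#' @param sim a [simulate_pangenome()] result.
#' @param a,b ordered pair of cultivar names.
#' @param flank flank width in bp (0 = gene body only; published sweep used
#'   0/1000/2000/5000).
#' @return 13-column HSP data frame.
#' @export
simulate_gene_alignments <- function(sim, a, b, flank = 2000) {
  spec <- sim$spec
  genes <- .gene_grid(spec)
  if (nrow(genes) == 0L) stop("spec has no genes")
  s <- pmax(1, genes$start - flank)
  e <- pmin(spec$chrom_len, genes$end + flank)
  ma <- sim$subst_maps[[a]]; mb <- sim$subst_maps[[b]]
  ia <- match(ma$pos, mb$pos)
  mpos <- sort(c(ma$pos[!is.na(ia) & ma$off != mb$off[ia]],
                 ma$pos[is.na(ia)], mb$pos[!mb$pos %in% ma$pos]))
  count_in <- function(iv_s, iv_e, pos)
    vapply(seq_along(iv_s), function(i)
      sum(pos >= iv_s[i] & pos <= iv_e[i]), numeric(1))
  n_in <- function(nrs, iv_s, iv_e) {
    out <- numeric(length(iv_s))
    for (i in seq_len(nrow(nrs))) {
      lo <- pmax(iv_s, nrs[i, 1]); hi <- pmin(iv_e, nrs[i, 2])
      out <- out + pmax(0, hi - lo + 1)
    }
    out
  }
  mism <- count_in(s, e, mpos)
  len <- e - s + 1
  qn <- n_in(sim$n_intervals[[a]], s, e)
  sn <- n_in(sim$n_intervals[[b]], s, e)
  data.frame(qseqid = genes$gene_id, sseqid = spec$chrom,
             pident = 100 * (1 - mism / len), length = len, mismatch = mism,
             gapopen = 0, qstart = 1, qend = len, sstart = s, send = e,
             bitscore = 2 * len, qNs = qn, sNs = sn,
             stringsAsFactors = FALSE)
}

#' Write every simulator output to a directory
#'
#' Emits, per ordered pair, a show-coords-dialect TSV; per cultivar, a GFF3
#' of gene projections (and FASTA when sequences were materialised); plus the
#' collated SNP TSV, genotype TSV and map, and the truth intervals as BED.
#'
#' @param sim a [simulate_pangenome()] result.
#' @param dir output directory (created if needed).
#' @param gene_aln_flank when non-NULL, also write per-pair gene-alignment
#'   tables at this flank width.
#' @return \code{dir}, invisibly.
#' @export
write_pangenome <- function(sim, dir, gene_aln_flank = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pair in names(sim$alignments)) {
    fn <- file.path(dir, paste0("coords_", gsub("|", "_", pair, fixed = TRUE),
                                ".tsv"))
    write_coords(sim$alignments[[pair]], fn)
  }
  for (cv in sim$spec$cultivars) {
    pr <- sim$projections[sim$projections$assembly == cv, , drop = FALSE]
    write_gff3_projections(pr, file.path(dir, paste0(cv, ".gff3")))
  }
  if (!is.null(sim$sequences)) {
    for (cv in names(sim$sequences)) {
      fa <- file.path(dir, paste0(cv, ".fa"))
      writeLines(c(paste0(">", sim$spec$chrom), sim$sequences[[cv]]), fa)
    }
  }
  snps <- collate_snps(sim$snps)
  utils::write.table(snps, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$genotypes))
    write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"),
                    file.path(dir, "marker_map.tsv"))
  tb <- haplotype_blocks(sim$truth$cultivar_a, sim$truth$cultivar_b,
                         sim$truth$chrom, sim$truth$start, sim$truth$end,
                         source = "truth")
  write_bed_blocks(tb, file.path(dir, "truth.bed"))
  if (!is.null(gene_aln_flank)) {
    for (pair in names(sim$alignments)) {
      ab <- strsplit(pair, "|", fixed = TRUE)[[1]]
      ga <- simulate_gene_alignments(sim, ab[1], ab[2], gene_aln_flank)
      write_blast_tab(ga, file.path(
        dir, paste0("blast_", ab[1], "_", ab[2], ".tsv")))
    }
  }
  invisible(dir)
}
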