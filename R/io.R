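# Internal coordinate convention: 1-based, fully inclusive, matching MUMmer and
# BLAST output. BED is the only 0-based half-open surface and conversion happens
# exclusively in write_bed_blocks()/read_bed_blocks().

#' Construct a table of pairwise alignment records
#'
#' The central alignment container: one row per aligned segment between a
#' reference and a query assembly. Reverse-strand alignments are encoded, as in
#' MUMmer's \code{show-coords}, by \code{query_start > query_end}; there is no
#' separate strand column.
#'
#' @param ref_name,query_name chromosome/scaffold identifiers.
#' @param ref_start,ref_end 1-based inclusive reference coordinates
#'   (\code{ref_end >= ref_start}).
#' @param query_start,query_end 1-based inclusive query coordinates;
#'   \code{query_start > query_end} encodes the reverse strand.
#' @param aln_length alignment length in bp (gapped columns included).
#' @param mismatches number of mismatching columns (SNPs plus small-indel
#'   columns).
#' @param n_count number of N positions within the aligned span.
#' @return a \code{data.frame} with one row per record and a derived
#'   \code{identity_pct} column (see [percent_identity()]).
#' @export
alignment_records <- function(ref_name, query_name, ref_start, ref_end,
                              query_start, query_end, aln_length, mismatches,
                              n_count = 0L) {
  df <- data.frame(
    ref_name = as.character(ref_name), query_name = as.character(query_name),
    ref_start = as.numeric(ref_start), ref_end = as.numeric(ref_end),
    query_start = as.numeric(query_start), query_end = as.numeric(query_end),
    aln_length = as.numeric(aln_length), mismatches = as.numeric(mismatches),
    n_count = as.numeric(n_count), stringsAsFactors = FALSE
  )
  if (any(df$ref_end < df$ref_start))
    stop("alignment records must satisfy ref_end >= ref_start")
  if (any(df$aln_length < 1))
    stop("alignment length must be >= 1")
  if (any(df$mismatches < 0 | df$mismatches > df$aln_length))
    stop("mismatches must lie in [0, aln_length]")
  df$identity_pct <- percent_identity(df$aln_length, df$mismatches)
  df
}

empty_alignment_records <- function() {
  alignment_records(character(), character(), numeric(), numeric(),
                    numeric(), numeric(), numeric(), numeric(), numeric())
}

.read_tab_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a show-coords style tabular alignment file
#'
#' Parses the tab-separated dialect produced by \code{show-coords -T}:
#' columns \code{S1 E1 S2 E2 LEN1 LEN2 \%IDY REF_TAG QUERY_TAG}. Files carrying
#' the two extra \code{LEN_R LEN_Q} columns of \code{show-coords -T -l}
#' (11 columns) are accepted and the length columns ignored. Header/banner
#' lines (anything whose first field is not a number) are tolerated and
#' skipped.
#'
#' @param path path to the coords file.
#' @return a record table as returned by [alignment_records()]. Mismatch counts
#'   are reconstructed from \code{\%IDY} as
#'   \code{round(LEN1 * (100 - \%IDY)/100)}; \code{n_count} is 0 (the format
#'   does not carry it).
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lt <- .read_tab_lines(path)
  fields <- strsplit(lt$lines, "\t", fixed = TRUE)
  first_num <- vapply(fields, function(f) {
    length(f) >= 1 && !is.na(suppressWarnings(as.numeric(f[[1]])))
  }, logical(1))
  data_idx <- which(first_num)
  if (length(data_idx) == 0L) {
    warning("no data rows in ", path)
    return(empty_alignment_records())
  }
  rows <- fields[data_idx]
  nf <- lengths(rows)
  bad <- which(!(nf == 9L | nf == 11L))
  if (length(bad))
    stop("malformed coords row at line ", lt$lineno[data_idx[bad[1]]],
         ": expected 9 (or 11 with LEN_R/LEN_Q) tab-separated fields, got ",
         nf[bad[1]])
  parse_row <- function(f, lineno) {
    if (length(f) == 11L) f <- f[-c(8L, 9L)]  # drop LEN_R LEN_Q
    num <- suppressWarnings(as.numeric(f[1:7]))
    if (anyNA(num))
      stop("malformed coords row at line ", lineno, ": non-numeric field")
    c(num, f[8:9])
  }
  parsed <- mapply(parse_row, rows, lt$lineno[data_idx], SIMPLIFY = FALSE)
  m <- do.call(rbind, parsed)
  s1 <- as.numeric(m[, 1]); e1 <- as.numeric(m[, 2])
  len1 <- as.numeric(m[, 5]); idy <- as.numeric(m[, 7])
  alignment_records(
    ref_name = m[, 8], query_name = m[, 9],
    ref_start = s1, ref_end = e1,
    query_start = as.numeric(m[, 3]), query_end = as.numeric(m[, 4]),
    aln_length = len1,
    mismatches = round(len1 * (100 - idy) / 100)
  )
}

#' Write alignment records as a show-coords style table
#'
#' Inverse of [read_coords()]; identities are printed with enough digits that
#' integer mismatch counts survive a round trip.
#'
#' @param records table from [alignment_records()].
#' @param path output path.
#' @export
write_coords <- function(records, path) {
  lines <- sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s\t%s",
                   as.integer(records$ref_start), as.integer(records$ref_end),
                   as.integer(records$query_start), as.integer(records$query_end),
                   as.integer(records$aln_length),
                   as.integer(abs(records$query_end - records$query_start) + 1),
                   formatC(records$identity_pct, format = "f", digits = 6),
                   records$ref_name, records$query_name)
  writeLines(c("S1\tE1\tS2\tE2\tLEN1\tLEN2\t%IDY\tREF_TAG\tQUERY_TAG", lines),
             path)
  invisible(path)
}

.blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "bitscore", "qNs", "sNs")

#' Read a 13-column BLAST tabular file with N counts
#'
#' Accepts the fixed dialect \code{qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send bitscore qNs sNs} (standard \code{-outfmt 6} minus
#' evalue, plus per-HSP N counts in the aligned query/subject sequence, which
#' the gene-window N filter needs). No filtering or HSP selection happens here;
#' several HSPs per (gene, pair) are preserved.
#'
#' @param path path to the tab-separated file.
#' @return a \code{data.frame} with the 13 columns above.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lt <- .read_tab_lines(path)
  lines <- lt$lines
  is_header <- grepl("^#", lines) | grepl("^qseqid\t", lines)
  lines <- lines[!is_header]
  if (length(lines) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), 13), .blast_cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 13L))
    stop("expected the 13-column BLAST dialect: ",
         paste(.blast_cols, collapse = " "),
         " (tab-separated); got ", nf[which(nf != 13L)[1]], " columns")
  m <- do.call(rbind, fields)
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                   pident = as.numeric(m[, 3]), length = as.numeric(m[, 4]),
                   mismatch = as.numeric(m[, 5]), gapopen = as.numeric(m[, 6]),
                   qstart = as.numeric(m[, 7]), qend = as.numeric(m[, 8]),
                   sstart = as.numeric(m[, 9]), send = as.numeric(m[, 10]),
                   bitscore = as.numeric(m[, 11]), qNs = as.numeric(m[, 12]),
                   sNs = as.numeric(m[, 13]), stringsAsFactors = FALSE)
  names(df) <- .blast_cols
  df
}

#' Write a 13-column BLAST tabular file
#' @param hsps data frame in the layout returned by [read_blast_tab()].
#' @param path output path.
#' @export
write_blast_tab <- function(hsps, path) {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%d\t%d",
                   hsps$qseqid, hsps$sseqid,
                   formatC(hsps$pident, format = "f", digits = 6),
                   as.integer(hsps$length), as.integer(hsps$mismatch),
                   as.integer(hsps$gapopen), as.integer(hsps$qstart),
                   as.integer(hsps$qend), as.integer(hsps$sstart),
                   as.integer(hsps$send),
                   formatC(hsps$bitscore, format = "f", digits = 1),
                   as.integer(hsps$qNs), as.integer(hsps$sNs))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene projections from a GFF3 file
#'
#' Extracts \code{gene} features and their \code{ID} attribute. Within the file,
#' genes are ranked per chromosome by start coordinate; when the file is the
#' reference annotation these ranks are the reference gene order used by the
#' window caller and the lifter. Genes appearing more than once (multiple
#' projections) are flagged in the \code{multi} column and every placement kept.
#'
#' @param path GFF3 path.
#' @param assembly assembly (cultivar) name recorded on every row.
#' @return a \code{data.frame} with columns \code{gene_id}, \code{assembly},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{ref_rank},
#'   \code{multi}.
#' @export
read_gff3_projections <- function(path, assembly) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(gene_projections(character(), assembly, character(),
                            numeric(), numeric(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GFF3 row (", nf[which(nf != 9L)[1]], " columns)")
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  gene_projections(gene_id = ids, assembly = assembly, chrom = m[, 1],
                   start = as.numeric(m[, 4]), end = as.numeric(m[, 5]),
                   strand = m[, 7])
}

#' Construct a gene-projection table
#'
#' @param gene_id,assembly,chrom,start,end,strand per-gene fields (1-based
#'   inclusive coordinates).
#' @param ref_rank optional precomputed reference rank; when missing, ranks are
#'   assigned per chromosome by start order (appropriate for the reference
#'   annotation itself).
#' @return projection \code{data.frame}; see [read_gff3_projections()].
#' @export
gene_projections <- function(gene_id, assembly, chrom, start, end, strand = "+",
                             ref_rank = NULL) {
  df <- data.frame(gene_id = as.character(gene_id),
                   assembly = rep_len(as.character(assembly), length(gene_id)),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(gene_id)),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$end < df$start)) stop("gene end < start")
  if (is.null(ref_rank)) {
    df$ref_rank <- NA_integer_
    for (ch in unique(df$chrom)) {
      i <- which(df$chrom == ch)
      df$ref_rank[i] <- rank(df$start[i], ties.method = "first")
    }
  } else {
    df$ref_rank <- as.integer(rep_len(ref_rank, length(gene_id)))
  }
  df$multi <- df$gene_id %in% df$gene_id[duplicated(df$gene_id)]
  df
}

#' Write gene projections as GFF3
#' @param projections table from [gene_projections()].
#' @param path output path.
#' @export
write_gff3_projections <- function(projections, path) {
  lines <- sprintf("%s\tpanhap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   projections$chrom, as.integer(projections$start),
                   as.integer(projections$end), projections$strand,
                   projections$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Construct a haplotype-block table
#'
#' @param ref_cultivar,query_cultivar assembly names of the ordered pair.
#' @param chrom chromosome id (reference coordinates).
#' @param start,end 1-based inclusive block bounds in reference coordinates.
#' @param source provenance: \code{"nucmer"}, \code{"blast"} or
#'   \code{"combined"}.
#' @param bin_size bin width used by the binned caller (NA for gene-window
#'   blocks).
#' @return block \code{data.frame}.
#' @export
haplotype_blocks <- function(ref_cultivar, query_cultivar, chrom, start, end,
                             source = "nucmer", bin_size = NA_real_) {
  df <- data.frame(ref_cultivar = as.character(ref_cultivar),
                   query_cultivar = as.character(query_cultivar),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   source = rep_len(as.character(source), length(start)),
                   bin_size = rep_len(as.numeric(bin_size), length(start)),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$end <= df$start)) stop("block end must exceed start")
  df
}

empty_blocks <- function() {
  haplotype_blocks(character(), character(), character(), numeric(), numeric(),
                   character(), numeric())
}

#' Write haplotype blocks as BED
#'
#' Internal 1-based inclusive intervals become 0-based half-open BED; the name
#' field encodes \code{ref|query|source|binsize}.
#'
#' @param blocks table from [haplotype_blocks()].
#' @param path output path.
#' @export
write_bed_blocks <- function(blocks, path) {
  header <- "track name=panhap_blocks"
  if (nrow(blocks) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(blocks$chrom, blocks$start)
  b <- blocks[ord, , drop = FALSE]
  name <- sprintf("%s|%s|%s|%s", b$ref_cultivar, b$query_cultivar, b$source,
                  ifelse(is.na(b$bin_size), "NA",
                         format(b$bin_size, scientific = FALSE, trim = TRUE)))
  lines <- sprintf("%s\t%d\t%d\t%s", b$chrom, as.integer(b$start - 1),
                   as.integer(b$end), name)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read haplotype blocks from BED written by [write_bed_blocks()]
#' @param path BED path.
#' @return block \code{data.frame}.
#' @export
read_bed_blocks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, fields)
  meta <- strsplit(m[, 4], "|", fixed = TRUE)
  mm <- do.call(rbind, meta)
  haplotype_blocks(ref_cultivar = mm[, 1], query_cultivar = mm[, 2],
                   chrom = m[, 1], start = as.numeric(m[, 2]) + 1,
                   end = as.numeric(m[, 3]), source = mm[, 3],
                   bin_size = suppressWarnings(as.numeric(mm[, 4])))
}

#' Construct a genotype matrix
#'
#' @param calls line x marker matrix; entries 0 (reference allele), 1
#'   (alternative) or NA (missing). Row names are line ids, column names marker
#'   ids.
#' @param markers data frame with \code{marker_id}, \code{chrom}, \code{pos}
#'   (bp) describing the columns, in column order.
#' @return an object of class \code{"genotype_matrix"}.
#' @export
genotype_matrix <- function(calls, markers) {
  calls <- as.matrix(calls)
  stopifnot(ncol(calls) == nrow(markers))
  if (is.null(colnames(calls))) colnames(calls) <- markers$marker_id
  stopifnot(identical(colnames(calls), as.character(markers$marker_id)))
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (is.unsorted(p)) stop("marker positions must be non-decreasing per chromosome")
  }
  structure(list(calls = calls, markers = markers), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "lines x", ncol(x$calls), "markers\n")
  invisible(x)
}

#' Read a genotype matrix from TSV
#'
#' First column is the line id; remaining columns are marker ids with calls in
#' \{0, 1, NA\}. Marker positions come either from a companion map file
#' (\code{marker_id chrom pos} TSV) or default to rank order on one chromosome.
#'
#' @param path genotype TSV.
#' @param map_path optional marker map TSV.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, map_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lines <- as.character(df[[1]])
  calls <- as.matrix(df[, -1, drop = FALSE])
  mode(calls) <- "numeric"
  rownames(calls) <- lines
  if (!is.null(map_path)) {
    map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
    names(map)[1:3] <- c("marker_id", "chrom", "pos")
    map <- map[match(colnames(calls), map$marker_id), ]
  } else {
    map <- data.frame(marker_id = colnames(calls), chrom = "chrUn",
                      pos = seq_len(ncol(calls)), stringsAsFactors = FALSE)
  }
  genotype_matrix(calls, map)
}

#' Write a genotype matrix as TSV (plus marker map)
#' @param gm a [genotype_matrix()].
#' @param path genotype TSV path.
#' @param map_path optional marker map output path.
#' @export
write_genotypes <- function(gm, path, map_path = NULL) {
  df <- data.frame(line = rownames(gm$calls), gm$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path))
    utils::write.table(gm$markers, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Construct a SNP record table
#'
#' @param ref_chrom,ref_pos reference chromosome and 1-based position.
#' @param ref_allele,alt_allele single-base alleles ("." or "N" mark calls to
#'   be filtered by [collate_snps()]).
#' @param query_assembly cultivar the alternative allele was observed in.
#' @param flank_seq optional sequence of 2*flank+1 bases centred on the SNP.
#' @return SNP \code{data.frame}.
#' @export
snp_records <- function(ref_chrom, ref_pos, ref_allele, alt_allele,
                        query_assembly, flank_seq = NA_character_) {
  data.frame(ref_chrom = as.character(ref_chrom), ref_pos = as.numeric(ref_pos),
             ref_allele = as.character(ref_allele),
             alt_allele = as.character(alt_allele),
             query_assembly = as.character(query_assembly),
             flank_seq = rep_len(as.character(flank_seq), length(ref_pos)),
             stringsAsFactors = FALSE)
}
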