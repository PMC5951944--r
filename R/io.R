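#' @import data.table
#' @importFrom stats optimize setNames quantile rnbinom rpois runif rgamma rmultinom cor
#' @importFrom utils head tail
NULL

# Internal coordinate convention: everything is 0-based half-open.
# BED is native; GTF is converted (+1, inclusive -> half-open) at the boundary.

#' Read a per-sample CTSS BED6 file
#'
#' A CTSS file holds single-nucleotide stranded CAGE 5'-end tag counts: one
#' BED6 row per (position, strand), with the integer tag count in the score
#' column. Coordinates are 0-based and left unchanged.
#'
#' @param path Path to a BED6 file.
#' @param sample_id Label attached to every record; defaults to the file name
#'   without extension.
#' @return A `data.table` with columns `chrom`, `pos`, `strand`, `count`,
#'   `sample_id`.
#' @export
read_ctss_bed <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (!file.exists(path)) stop("CTSS file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) {
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), count = integer(),
                      sample_id = character()))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed BED6 line ", which(nf < 6L)[1L], " in ", path,
         ": expected >= 6 tab-separated fields")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  count <- suppressWarnings(as.numeric(m[, 5L]))
  bad <- which(is.na(start) | is.na(end) | is.na(count))
  if (length(bad)) {
    stop("malformed BED6 line ", bad[1L], " in ", path,
         ": non-numeric coordinate or score")
  }
  if (any(m[, 6L] != "+" & m[, 6L] != "-")) {
    stop("invalid strand on line ", which(m[, 6L] != "+" & m[, 6L] != "-")[1L],
         " in ", path, " (must be '+' or '-')")
  }
  if (any(count < 0)) {
    stop("negative tag count on line ", which(count < 0)[1L], " in ", path)
  }
  if (any(count != floor(count))) {
    stop("non-integer tag count on line ", which(count != floor(count))[1L],
         " in ", path)
  }
  if (any(end != start + 1L)) {
    stop("line ", which(end != start + 1L)[1L], " in ", path,
         " is not single-nucleotide (end must equal start + 1)")
  }
  out <- data.table(chrom = m[, 1L], pos = start, strand = m[, 6L],
                    count = as.integer(count), sample_id = sample_id)
  if (anyDuplicated(out, by = c("chrom", "pos", "strand"))) {
    stop("duplicate (chrom, pos, strand) records in ", path)
  }
  out[]
}

#' Write a CTSS table as BED6
#'
#' Inverse of [read_ctss_bed()]: one row per (position, strand) with the tag
#' count in the score column. Records are sorted by (chrom, pos, strand) so
#' output is deterministic.
#'
#' @param ctss `data.table` with `chrom`, `pos`, `strand`, `count`.
#' @param path Output path.
#' @export
write_ctss_bed <- function(ctss, path) {
  stopifnot(all(c("chrom", "pos", "strand", "count") %in% names(ctss)))
  ctss <- as.data.table(ctss)[count >= 1L]
  setorder(ctss, chrom, pos, strand)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   ctss$chrom, ctss$pos, ctss$pos + 1L,
                   paste0(ctss$chrom, ":", ctss$pos, ":", ctss$strand),
                   ctss$count, ctss$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read protein-coding gene models from a GTF file
#'
#' Parses transcript and exon (and optional CDS) rows, converting the GTF's
#' 1-based inclusive coordinates to 0-based half-open. The TSS of each
#' transcript is the low coordinate on the + strand and the high coordinate
#' minus one on the - strand.
#'
#' @param path GTF file path.
#' @param feature_filter Keep only transcripts whose `gene_biotype` (or
#'   `gene_type`) attribute equals this value; `NULL` keeps everything.
#' @return A list with `transcripts` (one row per transcript: `tx_id`,
#'   `gene_id`, `gene_name`, `chrom`, `strand`, `start`, `end`, `tss`,
#'   `cds_start`, `cds_end`) and `exons` (`tx_id`, `start`, `end`), all
#'   0-based half-open.
#' @export
read_gtf <- function(path, feature_filter = "protein_coding") {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  strand <- as.character(df$strand)
  if (any(strand == "*")) {
    warning("skipping ", sum(strand == "*"), " GTF rows with unknown strand")
    df <- df[strand != "*", , drop = FALSE]
    strand <- strand[strand != "*"]
  }
  biotype_col <- intersect(c("gene_biotype", "gene_type"), names(df))
  if (!is.null(feature_filter) && length(biotype_col)) {
    keep <- df[[biotype_col[1L]]] %in% feature_filter
    df <- df[keep, , drop = FALSE]
  }
  dt <- data.table(
    type = as.character(df$type), chrom = as.character(df$seqnames),
    start = as.integer(df$start) - 1L, end = as.integer(df$end),
    strand = as.character(df$strand),
    gene_id = as.character(df$gene_id),
    tx_id = if ("transcript_id" %in% names(df)) as.character(df$transcript_id) else NA_character_,
    gene_name = if ("gene_name" %in% names(df)) as.character(df$gene_name) else as.character(df$gene_id)
  )
  tx <- dt[type == "transcript"]
  if (nrow(tx) == 0L) {
    # fall back to gene rows as single-exon transcripts
    tx <- dt[type == "gene"]
    tx[, tx_id := gene_id]
  }
  exons <- dt[type == "exon" & !is.na(tx_id)]
  cds <- dt[type == "CDS" & !is.na(tx_id)]
  if (nrow(exons)) {
    span <- tx[, .(tx_id, tx_start = start, tx_end = end)]
    ex <- merge(exons, span, by = "tx_id")
    bad <- ex[start < tx_start | end > tx_end]
    if (nrow(bad)) {
      stop("exon outside transcript span for transcript ", bad$tx_id[1L])
    }
  }
  if (nrow(cds)) {
    cds_span <- cds[, .(cds_start = min(start), cds_end = max(end)), by = tx_id]
  } else {
    cds_span <- data.table(tx_id = character(), cds_start = integer(),
                           cds_end = integer())
  }
  transcripts <- tx[, .(tx_id, gene_id, gene_name, chrom, strand, start, end)]
  transcripts <- merge(transcripts, cds_span, by = "tx_id", all.x = TRUE)
  transcripts[, tss := ifelse(strand == "+", start, end - 1L)]
  exon_tab <- if (nrow(exons)) exons[, .(tx_id, start, end)] else
    transcripts[, .(tx_id, start, end)]
  setorder(exon_tab, tx_id, start)
  # exon invariants: sorted, non-overlapping within transcript
  ov <- exon_tab[, .(bad = any(head(end, -1) > tail(start, -1))), by = tx_id]
  if (any(ov$bad)) stop("overlapping exons in transcript ", ov[bad == TRUE, tx_id][1L])
  setorder(transcripts, chrom, start, tx_id)
  list(transcripts = transcripts[], exons = exon_tab[])
}

#' Write gene models as GTF
#'
#' Inverse of [read_gtf()] for the model list it returns; coordinates are
#' converted back to 1-based inclusive. Output row order is deterministic.
#'
#' @param models List with `transcripts` and `exons` as from [read_gtf()].
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  tx <- as.data.table(models$transcripts)
  ex <- as.data.table(models$exons)
  setorder(tx, chrom, start, tx_id)
  rows <- character(0)
  attr_of <- function(t) sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "protein_coding";',
    t$gene_id, t$tx_id, t$gene_name)
  for (i in seq_len(nrow(tx))) {
    t <- tx[i]
    a <- attr_of(t)
    rows <- c(rows, sprintf("%s\tbidiCAGE\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                            t$chrom, t$start + 1L, t$end, t$strand, a))
    exi <- ex[tx_id == t$tx_id][order(start)]
    for (j in seq_len(nrow(exi))) {
      rows <- c(rows, sprintf("%s\tbidiCAGE\texon\t%d\t%d\t.\t%s\t.\t%s",
                              t$chrom, exi$start[j] + 1L, exi$end[j], t$strand, a))
    }
    if (!is.na(t$cds_start)) {
      rows <- c(rows, sprintf("%s\tbidiCAGE\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              t$chrom, t$cds_start + 1L, t$cds_end, t$strand, a))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a region set (BED3/BED6), e.g. permissive enhancer regions
#'
#' @param path BED file path.
#' @param name Label for the set.
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_regions_bed <- function(path, name = basename(path)) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) {
    out <- data.table(chrom = character(), start = integer(), end = integer())
  } else {
    fields <- strsplit(raw, "\t", fixed = TRUE)
    if (any(lengths(fields) < 3L)) {
      stop("malformed BED line ", which(lengths(fields) < 3L)[1L], " in ", path)
    }
    out <- data.table(chrom = vapply(fields, `[`, "", 1L),
                      start = as.integer(vapply(fields, `[`, "", 2L)),
                      end = as.integer(vapply(fields, `[`, "", 3L)))
  }
  if (any(out$start >= out$end)) {
    stop("invalid interval (start >= end) on line ",
         which(out$start >= out$end)[1L], " in ", path)
  }
  setattr(out, "region_set_name", name)
  out[]
}

#' Write a region set as BED3
#' @param regions `data.table` with `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  regions <- as.data.table(regions)
  setorder(regions, chrom, start, end)
  writeLines(sprintf("%s\t%d\t%d", regions$chrom, regions$start, regions$end),
             path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `condition` (control/stimulated)
#' and optionally `path` to the sample's CTSS BED.
#'
#' @param path TSV path.
#' @return `data.table` with a `replicate` index added within condition.
#' @export
read_sample_sheet <- function(path) {
  ss <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = "sample_id"))
  if (!all(c("sample_id", "condition") %in% names(ss))) {
    stop("sample sheet must have columns sample_id and condition")
  }
  if (!all(ss$condition %in% c("control", "stimulated"))) {
    stop("condition must be 'control' or 'stimulated'")
  }
  if (any(table(ss$condition) < 2L)) {
    stop("need >= 2 samples per condition for differential testing")
  }
  ss[, replicate := seq_len(.N), by = condition]
  ss[]
}

# Table-1-style annotated locus output ----------------------------------------

result_columns <- c("locus_id", "gene_symbol", "annotation", "gene_strand",
                    "distance_to_tss", "fdr_plus", "fdr_minus",
                    "permissive_enhancer", "strand_class")

#' Write annotated eRNA candidate loci as TSV
#'
#' One row per locus with the candidate-table schema: nearest gene symbol,
#' genomic annotation category, gene strand, signed distance to the nearest
#' protein-coding TSS, per-strand FDR, enhancer-set overlap flag (`+`/`-`)
#' and the strand significance class.
#'
#' @param records `data.table` of annotated loci (see [annotate_loci()]).
#' @param path Output path.
#' @export
write_results_tsv <- function(records, path) {
  records <- as.data.table(records)
  out <- data.table(locus_id = character(), gene_symbol = character(),
                    annotation = character(), gene_strand = character(),
                    distance_to_tss = integer(), fdr_plus = numeric(),
                    fdr_minus = numeric(), permissive_enhancer = character(),
                    strand_class = character())
  if (nrow(records)) {
    out <- records[, .(locus_id, gene_symbol, annotation, gene_strand,
                       distance_to_tss,
                       fdr_plus = signif(fdr_plus, 8),
                       fdr_minus = signif(fdr_minus, 8),
                       permissive_enhancer = ifelse(permissive_enhancer, "+", "-"),
                       strand_class)]
  }
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results_tsv()]
#' @param path TSV path.
#' @return `data.table` with the enhancer flag decoded back to logical.
#' @export
read_results_tsv <- function(path) {
  out <- fread(path, sep = "\t", header = TRUE,
               colClasses = list(character = c("locus_id", "gene_symbol",
                                               "annotation", "gene_strand",
                                               "permissive_enhancer",
                                               "strand_class")))
  if (!all(result_columns %in% names(out))) {
    stop("not a results TSV: missing columns in ", path)
  }
  out[, permissive_enhancer := permissive_enhancer == "+"]
  out[]
}
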