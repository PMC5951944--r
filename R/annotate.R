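# Genomic annotation of anchors: signed distance to the nearest
# protein-coding TSS, feature category, enhancer-set overlap.

feature_categories <- c("Promoter (<=1 kb)", "Promoter (1-2 kb)",
                        "Promoter (2-3 kb)", "5' UTR", "3' UTR", "Exon",
                        "Intron", "Downstream (<=3 kb)", "Distal Intergenic")

#' Signed distance from anchors to the nearest protein-coding TSS
#'
#' The nearest TSS is chosen by absolute genomic distance over all
#' protein-coding transcript TSSs on the anchor's chromosome. The signed
#' distance is expressed in the gene's own orientation:
#' `d = anchor - tss` for + strand genes and `d = tss - anchor` for - strand
#' genes, so `d < 0` is upstream and `d > 0` downstream of the gene. Ties in
#' absolute distance are broken toward the lexicographically smallest
#' `gene_id`.
#'
#' @param anchors `data.table` with `chrom` and `pos`.
#' @param models Gene model list from [read_gtf()] / [simulate_gene_models()].
#' @return `data.table`: `chrom`, `pos`, `gene_id`, `gene_symbol`,
#'   `gene_strand`, `tss`, `distance_to_tss`.
#' @export
distance_to_tss <- function(anchors, models) {
  tx <- as.data.table(models$transcripts)
  if (nrow(tx) == 0L) stop("empty gene model set")
  anchors <- as.data.table(anchors)[, .(chrom, pos)]
  tss_tab <- tx[, .(chrom, tss, gene_id, gene_name, strand)]
  setorder(tss_tab, chrom, tss, gene_id)
  out <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    cand <- tss_tab[chrom == anchors$chrom[i]]
    if (nrow(cand) == 0L) cand <- tss_tab  # fall back to genome-wide search
    ad <- abs(anchors$pos[i] - cand$tss)
    best <- cand[ad == min(ad)][order(gene_id)][1L]
    d <- if (best$strand == "+") anchors$pos[i] - best$tss
         else best$tss - anchors$pos[i]
    out[[i]] <- data.table(chrom = anchors$chrom[i], pos = anchors$pos[i],
                           gene_id = best$gene_id, gene_symbol = best$gene_name,
                           gene_strand = best$strand, tss = best$tss,
                           distance_to_tss = as.integer(d))
  }
  rbindlist(out)
}

# Build the interval layers used by the category priority as GRanges.
annotation_layers <- function(models) {
  tx <- as.data.table(models$transcripts)
  ex <- as.data.table(models$exons)
  gr <- function(dt) {
    if (nrow(dt) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(dt$chrom,
                           IRanges::IRanges(dt$start + 1L, dt$end))
  }
  ex2 <- merge(ex, tx[, .(tx_id, chrom, strand, cds_start, cds_end,
                          tx_start = start, tx_end = end)], by = "tx_id")
  # UTRs: exon parts outside the CDS span, sided by strand
  with_cds <- ex2[!is.na(cds_start)]
  utr5 <- rbind(
    with_cds[strand == "+" & start < cds_start,
             .(chrom, start, end = pmin(end, cds_start))],
    with_cds[strand == "-" & end > cds_end,
             .(chrom, start = pmax(start, cds_end), end)])
  utr3 <- rbind(
    with_cds[strand == "+" & end > cds_end,
             .(chrom, start = pmax(start, cds_end), end)],
    with_cds[strand == "-" & start < cds_start,
             .(chrom, start, end = pmin(end, cds_start))])
  list(utr5 = gr(utr5), utr3 = gr(utr3),
       exons = gr(ex2[, .(chrom, start, end)]),
       genes = gr(tx[, .(chrom, start, end)]),
       tx = tx)
}

#' Genomic feature category of anchors
#'
#' Priority order: (1) within `promoter_window` of any TSS, sub-binned by
#' absolute distance into `Promoter (<=1 kb)` / `(1-2 kb)` / `(2-3 kb)`;
#' (2) 5' UTR; (3) 3' UTR; (4) exon; (5) intron (inside a gene span but no
#' exon); (6) within `downstream_window` past a gene 3' end in gene
#' orientation; (7) `Distal Intergenic`.
#'
#' @param anchors `data.table` with `chrom`, `pos` (optionally the output of
#'   [distance_to_tss()], whose `distance_to_tss` column is then reused).
#' @param models Gene model list.
#' @param promoter_window,downstream_window Window sizes in bp (default
#'   3000 each).
#' @return Character vector of categories, one per anchor.
#' @export
annotate_feature <- function(anchors, models, promoter_window = 3000L,
                             downstream_window = 3000L) {
  anchors <- as.data.table(anchors)
  if (!"distance_to_tss" %in% names(anchors)) {
    anchors <- distance_to_tss(anchors, models)
  }
  layers <- annotation_layers(models)
  n <- nrow(anchors)
  if (n == 0L) return(character(0))
  apos <- GenomicRanges::GRanges(anchors$chrom,
                                 IRanges::IRanges(anchors$pos + 1L,
                                                  anchors$pos + 1L))
  hit <- function(gr) GenomicRanges::countOverlaps(apos, gr) > 0L
  tx <- layers$tx
  down <- tx[, .(chrom,
                 start = ifelse(strand == "+", end,
                                pmax(0L, start - downstream_window)),
                 end = ifelse(strand == "+", end + downstream_window, start))]
  down <- down[start < end]
  down_gr <- if (nrow(down)) GenomicRanges::GRanges(
    down$chrom, IRanges::IRanges(down$start + 1L, down$end)) else
    GenomicRanges::GRanges()
  ad <- abs(anchors$distance_to_tss)
  out <- rep("Distal Intergenic", n)
  in_down <- hit(down_gr)
  out[in_down] <- "Downstream (<=3 kb)"
  in_gene <- hit(layers$genes)
  out[in_gene] <- "Intron"
  in_exon <- hit(layers$exons)
  out[in_exon] <- "Exon"
  out[hit(layers$utr3)] <- "3' UTR"
  out[hit(layers$utr5)] <- "5' UTR"
  prom <- ad <= promoter_window
  out[prom & ad <= 3000] <- "Promoter (2-3 kb)"
  out[prom & ad <= 2000] <- "Promoter (1-2 kb)"
  out[prom & ad <= 1000] <- "Promoter (<=1 kb)"
  # promoter bins beyond 3 kb only matter for non-default windows
  if (promoter_window > 3000L) out[prom & ad > 3000] <- "Promoter (2-3 kb)"
  out
}

#' Does each anchor overlap a region set?
#'
#' Half-open semantics: anchor `p` overlaps `[start, end)` iff
#' `start <= p < end`.
#'
#' @param anchors `data.table` with `chrom`, `pos`.
#' @param regions Region `data.table` from [read_regions_bed()].
#' @return Logical vector, one per anchor.
#' @export
overlap_enhancers <- function(anchors, regions) {
  anchors <- as.data.table(anchors)
  regions <- as.data.table(regions)
  if (nrow(anchors) == 0L) return(logical(0))
  if (nrow(regions) == 0L) return(rep(FALSE, nrow(anchors)))
  apos <- GenomicRanges::GRanges(anchors$chrom,
                                 IRanges::IRanges(anchors$pos + 1L,
                                                  anchors$pos + 1L))
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1L,
                                                 regions$end))
  GenomicRanges::countOverlaps(apos, rgr) > 0L
}

#' Category fractions for increased vs decreased anchor sets
#'
#' @param increased,decreased Character vectors of feature categories.
#' @return `data.table` with one row per category and set, plus a merged
#'   `proximal promoter` row per set (sum of the three promoter bins).
#' @export
summarize_annotation <- function(increased, decreased) {
  for (nm in c("increased", "decreased")) {
    if (length(get(nm)) == 0L) stop("empty category set: ", nm)
  }
  one <- function(x, set) {
    f <- as.numeric(table(factor(x, levels = feature_categories))) / length(x)
    dt <- data.table(set = set, category = feature_categories, fraction = f)
    rbind(dt, data.table(set = set, category = "proximal promoter",
                         fraction = sum(f[1:3])))
  }
  rbind(one(increased, "increased"), one(decreased, "decreased"))
}

#' Annotate bidirectional loci (Table-1-style rows)
#'
#' Distance anchor is the locus midpoint. Adds nearest gene, signed distance
#' to its TSS, feature category and enhancer-set overlap flag to each locus.
#'
#' @param loci Classified loci from [classify_strand_significance()].
#' @param models Gene model list.
#' @param enhancers Optional region `data.table`; `NULL` means no overlap
#'   flags (all `FALSE`).
#' @param promoter_window,downstream_window Passed to [annotate_feature()].
#' @return Loci table extended with annotation columns.
#' @export
annotate_loci <- function(loci, models, enhancers = NULL,
                          promoter_window = 3000L, downstream_window = 3000L) {
  loci <- copy(as.data.table(loci))
  if (nrow(loci) == 0L) {
    loci[, `:=`(gene_symbol = character(), gene_strand = character(),
                distance_to_tss = integer(), annotation = character(),
                permissive_enhancer = logical())]
    return(loci[])
  }
  anchors <- loci[, .(chrom, pos = midpoint)]
  nn <- distance_to_tss(anchors, models)
  loci[, gene_symbol := nn$gene_symbol]
  loci[, gene_strand := nn$gene_strand]
  loci[, distance_to_tss := nn$distance_to_tss]
  loci[, annotation := annotate_feature(nn, models,
                                        promoter_window = promoter_window,
                                        downstream_window = downstream_window)]
  loci[, permissive_enhancer := if (is.null(enhancers)) FALSE else
    overlap_enhancers(anchors, enhancers)]
  loci[]
}
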