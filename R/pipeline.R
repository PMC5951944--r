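# End-to-end orchestration: merge -> cluster -> QC -> DE -> pairing ->
# classification -> annotation. The pipeline is a pure function of
# (dataset, config); repeated runs are identical.

#' Pipeline configuration
#'
#' All tunables with their defaults: clustering gap 20 bp and pooled-TPM
#' floor 0.5; DE FDR threshold 0.1; bidirectional pairing gap 300 bp;
#' per-strand fold screen 10; promoter/downstream annotation windows
#' 3000 bp; pseudo-count 0.25.
#'
#' @param max_gap_cluster,min_pooled_tpm Clustering parameters.
#' @param de_alpha FDR threshold.
#' @param bidir_max_gap Maximum divergent anchor distance.
#' @param min_fold Per-strand response threshold.
#' @param response_mode `"fold"` or `"difference"` (see
#'   [classify_strand_significance()]).
#' @param promoter_window,downstream_window Annotation windows.
#' @param pseudocount Pseudo-count on the normalized-TPM scale.
#' @param tagwise Use tagwise (shrunken) dispersions?
#' @param qc_transform Correlation transform.
#' @param match_window Recovery-scoring midpoint window.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_gap_cluster = 20L, min_pooled_tpm = 0.5,
                            de_alpha = 0.1, bidir_max_gap = 300L,
                            min_fold = 10, response_mode = "fold",
                            promoter_window = 3000L,
                            downstream_window = 3000L, pseudocount = 0.25,
                            tagwise = FALSE, qc_transform = "log1p",
                            match_window = 100L) {
  cfg <- as.list(environment())
  stopifnot(cfg$max_gap_cluster >= 0, cfg$bidir_max_gap >= 0,
            cfg$de_alpha > 0, cfg$de_alpha < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full eRNA discovery pipeline on in-memory inputs
#'
#' @param ctss_list Named list of per-sample CTSS tables.
#' @param conditions Named vector sample_id -> condition
#'   (`control`/`stimulated`).
#' @param models Gene model list (or `NULL` to skip annotation).
#' @param enhancers Optional enhancer region `data.table`.
#' @param config A `pipeline_config`.
#' @return List with every stage's output: `ctss` (merged table),
#'   `correlation`, `clusters`, `norm`, `dispersion`, `de`, `loci`
#'   (classified + annotated), `venn`, `annotation_summary`, `stage_counts`.
#' @export
run_pipeline <- function(ctss_list, conditions, models = NULL,
                         enhancers = NULL, config = pipeline_config()) {
  ctss <- merge_samples(ctss_list)
  corr <- pairwise_correlation(ctss, transform = config$qc_transform)
  clusters <- cluster_ctss(ctss, max_gap = config$max_gap_cluster,
                           min_pooled_tpm = config$min_pooled_tpm)
  cm <- count_matrix(clusters)
  groups <- unname(conditions[colnames(cm$counts)])
  norm <- tmm_factors(cm$counts, library_size = cm$library_size)
  disp <- estimate_common_dispersion(cm$counts, groups, norm = norm,
                                     tagwise = config$tagwise)
  de <- de_table(cm$counts, groups, disp, norm = norm,
                 pseudocount = config$pseudocount, alpha = config$de_alpha)
  loci <- pair_bidirectional(clusters, max_gap = config$bidir_max_gap)
  loci <- classify_strand_significance(
    loci, de, min_fold = config$min_fold, alpha = config$de_alpha,
    pseudocount = config$pseudocount, mode = config$response_mode)
  if (!is.null(models) && nrow(models$transcripts) > 0L && nrow(loci) > 0L) {
    loci <- annotate_loci(loci, models, enhancers,
                          promoter_window = config$promoter_window,
                          downstream_window = config$downstream_window)
  }
  venn <- venn_summary(loci)
  ann_summary <- NULL
  if (!is.null(models) && nrow(models$transcripts) > 0L) {
    cl <- clusters$clusters
    de_dir <- de[match(cl$cluster_id, cluster_id), direction]
    anch <- cl[, .(chrom, pos = dominant_pos)]
    cats <- annotate_feature(anch, models,
                             promoter_window = config$promoter_window,
                             downstream_window = config$downstream_window)
    inc <- cats[de_dir == "increased"]; dec <- cats[de_dir == "decreased"]
    if (length(inc) && length(dec)) {
      ann_summary <- summarize_annotation(inc, dec)
    }
  }
  list(ctss = ctss, correlation = corr, clusters = clusters, norm = norm,
       dispersion = disp, de = de, loci = loci, venn = venn,
       annotation_summary = ann_summary,
       stage_counts = list(
         n_ctss = nrow(ctss$index),
         n_clusters = nrow(clusters$clusters),
         n_increased = sum(de$direction == "increased"),
         n_decreased = sum(de$direction == "decreased"),
         n_candidate_loci = venn$n_total_loci,
         n_plus_only = venn$n_plus_only,
         n_minus_only = venn$n_minus_only,
         n_bidirectional = venn$n_bidirectional))
}

#' Run the pipeline on a dataset directory
#'
#' Reads the sample sheet, CTSS BEDs, GTF and optional enhancer BED written
#' by [simulate_dataset()] (or assembled by hand in the same layout), runs
#' [run_pipeline()] and writes every intermediate table under `out_dir`.
#'
#' @param dataset_dir Directory with `samples.tsv`, CTSS BEDs, `genes.gtf`
#'   and optionally `enhancers.bed`.
#' @param out_dir Results directory (created).
#' @param config A `pipeline_config`.
#' @return The [run_pipeline()] result list, invisibly extended with
#'   `out_dir`.
#' @export
run_pipeline_dir <- function(dataset_dir, out_dir,
                             config = pipeline_config()) {
  ss <- read_sample_sheet(file.path(dataset_dir, "samples.tsv"))
  ctss_list <- lapply(seq_len(nrow(ss)), function(i)
    read_ctss_bed(file.path(dataset_dir, ss$path[i]), ss$sample_id[i]))
  names(ctss_list) <- ss$sample_id
  conditions <- setNames(ss$condition, ss$sample_id)
  gtf <- file.path(dataset_dir, "genes.gtf")
  models <- if (file.exists(gtf)) read_gtf(gtf) else NULL
  enh_path <- file.path(dataset_dir, "enhancers.bed")
  enhancers <- if (file.exists(enh_path)) read_regions_bed(enh_path) else NULL
  res <- run_pipeline(ctss_list, conditions, models, enhancers, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(data.table(sample_id = res$correlation$sample_ids,
                    round(res$correlation$r, 6)),
         file.path(out_dir, "correlation.tsv"), sep = "\t", quote = FALSE)
  write_clusters_bed(res$clusters, file.path(out_dir, "clusters.bed"))
  cm <- data.table(cluster_id = rownames(res$clusters$counts),
                   res$clusters$counts)
  fwrite(cm, file.path(out_dir, "count_matrix.tsv"), sep = "\t",
         quote = FALSE)
  fwrite(res$de, file.path(out_dir, "diffexp.tsv"), sep = "\t",
         quote = FALSE)
  fwrite(res$loci, file.path(out_dir, "loci.tsv"), sep = "\t", quote = FALSE)
  if ("annotation" %in% names(res$loci)) {
    write_results_tsv(res$loci, file.path(out_dir, "candidates.tsv"))
  }
  fwrite(as.data.table(res$venn), file.path(out_dir, "venn_summary.tsv"),
         sep = "\t", quote = FALSE)
  if (!is.null(res$annotation_summary)) {
    fwrite(res$annotation_summary,
           file.path(out_dir, "annotation_summary.tsv"), sep = "\t",
           quote = FALSE)
  }
  counts_line <- vapply(res$stage_counts, as.integer, 0L)
  fwrite(data.table(stage = names(counts_line), n = counts_line),
         file.path(out_dir, "stage_counts.tsv"), sep = "\t", quote = FALSE)
  res$out_dir <- out_dir
  invisible(res)
}
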