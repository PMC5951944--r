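# Pairing divergent minus/plus TSS clusters into bidirectional loci and
# classifying them by per-strand fold change and significance.

#' Pair divergent minus/plus clusters within a maximum gap
#'
#' Candidate pairs are a minus-strand cluster m and a plus-strand cluster p
#' on the same chromosome with `0 <= anchor(p) - anchor(m) <= max_gap`
#' (divergent geometry: the minus transcript runs leftward from m, the plus
#' transcript rightward from p). Anchors are dominant positions. Pairs are
#' accepted greedily in ascending gap order with deterministic tie-breaks by
#' (chrom, minus anchor, plus anchor); a cluster is used at most once.
#'
#' @param cluster_set A `cluster_set` from [cluster_ctss()].
#' @param max_gap Maximum anchor distance in bp (default 300).
#' @return `data.table` of loci: `locus_id`, `chrom`, `minus_cluster_id`,
#'   `plus_cluster_id`, `minus_anchor`, `plus_anchor`, `gap`, `midpoint`.
#' @export
pair_bidirectional <- function(cluster_set, max_gap = 300L) {
  cl <- cluster_set$clusters
  minus <- cl[strand == "-", .(minus_cluster_id = cluster_id, chrom,
                               minus_anchor = dominant_pos)]
  plus <- cl[strand == "+", .(plus_cluster_id = cluster_id, chrom,
                              plus_anchor = dominant_pos)]
  empty <- data.table(locus_id = character(), chrom = character(),
                      minus_cluster_id = character(),
                      plus_cluster_id = character(),
                      minus_anchor = integer(), plus_anchor = integer(),
                      gap = integer(), midpoint = integer())
  if (nrow(minus) == 0L || nrow(plus) == 0L) return(empty)
  cand <- minus[plus, on = "chrom", allow.cartesian = TRUE, nomatch = NULL]
  cand <- cand[plus_anchor - minus_anchor >= 0L &
                 plus_anchor - minus_anchor <= max_gap]
  if (nrow(cand) == 0L) return(empty)
  cand[, gap := plus_anchor - minus_anchor]
  setorder(cand, gap, chrom, minus_anchor, plus_anchor)
  used_m <- character(0); used_p <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    m <- cand$minus_cluster_id[i]; p <- cand$plus_cluster_id[i]
    if (!(m %in% used_m) && !(p %in% used_p)) {
      keep[i] <- TRUE
      used_m <- c(used_m, m); used_p <- c(used_p, p)
    }
  }
  loci <- cand[keep]
  setorder(loci, chrom, minus_anchor, plus_anchor)
  loci[, midpoint := as.integer(floor((minus_anchor + plus_anchor) / 2))]
  loci[, locus_id := sprintf("locus_%s_%d", chrom, midpoint)]
  loci[, .(locus_id, chrom, minus_cluster_id, plus_cluster_id,
           minus_anchor, plus_anchor, gap, midpoint)]
}

#' Classify loci by per-strand response
#'
#' A strand of a locus "passes" iff its condition response exceeds
#' `min_fold` and its FDR is below `alpha`. In the default `"fold"` mode the
#' response is the ratio `(stimulated mean + pc) / (control mean + pc)` of
#' TMM-normalized mean TPM; `"difference"` mode uses the absolute difference
#' of the same means instead. Class is `bidirectional` if both strands pass,
#' `plus_only` / `minus_only` if exactly one passes, `none` otherwise.
#'
#' @param loci `data.table` from [pair_bidirectional()].
#' @param de DE table from [de_table()] (must cover all member clusters).
#' @param min_fold Response threshold (default 10).
#' @param alpha FDR threshold (default 0.1).
#' @param pseudocount Added to each condition mean in fold mode.
#' @param mode `"fold"` (ratio, default) or `"difference"` (absolute).
#' @return The loci table with per-strand fold, FDR and `strand_class`.
#' @export
classify_strand_significance <- function(loci, de, min_fold = 10,
                                         alpha = 0.1, pseudocount = 0.25,
                                         mode = c("fold", "difference")) {
  mode <- match.arg(mode)
  loci <- copy(as.data.table(loci))
  if (nrow(loci) == 0L) {
    loci[, `:=`(fold_plus = numeric(), fold_minus = numeric(),
                fdr_plus = numeric(), fdr_minus = numeric(),
                strand_class = character())]
    return(loci[])
  }
  de <- as.data.table(de)
  im <- match(loci$minus_cluster_id, de$cluster_id)
  ip <- match(loci$plus_cluster_id, de$cluster_id)
  if (anyNA(im) || anyNA(ip)) {
    stop("missing DE result for cluster(s): ",
         paste(head(c(loci$minus_cluster_id[is.na(im)],
                      loci$plus_cluster_id[is.na(ip)]), 3L), collapse = ", "))
  }
  response <- function(idx) {
    if (mode == "fold") {
      (de$mean_tpm_stimulated[idx] + pseudocount) /
        (de$mean_tpm_control[idx] + pseudocount)
    } else {
      de$mean_tpm_stimulated[idx] - de$mean_tpm_control[idx]
    }
  }
  loci[, fold_minus := response(im)]
  loci[, fold_plus := response(ip)]
  loci[, fdr_minus := de$fdr[im]]
  loci[, fdr_plus := de$fdr[ip]]
  pass_m <- loci$fold_minus > min_fold & loci$fdr_minus < alpha
  pass_p <- loci$fold_plus > min_fold & loci$fdr_plus < alpha
  loci[, strand_class := fifelse(pass_m & pass_p, "bidirectional",
                          fifelse(pass_p, "plus_only",
                           fifelse(pass_m, "minus_only", "none")))]
  loci[]
}

#' Venn-style summary of strand classes
#'
#' Counts of plus-only, minus-only and bidirectional loci (exclusive
#' buckets); loci of class `none` are excluded from the three buckets but
#' counted in the total.
#'
#' @param loci Classified loci table.
#' @return List with `n_plus_only`, `n_minus_only`, `n_bidirectional`,
#'   `n_total_loci`.
#' @export
venn_summary <- function(loci) {
  cls <- if (nrow(loci)) loci$strand_class else character(0)
  list(n_plus_only = sum(cls == "plus_only"),
       n_minus_only = sum(cls == "minus_only"),
       n_bidirectional = sum(cls == "bidirectional"),
       n_total_loci = length(cls))
}
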