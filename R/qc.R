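# Replicate quality control: all-pairs Pearson correlation of CTSS counts.

#' Pairwise Pearson correlation between samples at CTSS resolution
#'
#' Correlations are computed over the union of CTSS positions (zeros
#' included) for every unordered sample pair. The default transform is
#' `log1p` of TPM, which stabilises the heavy-tailed count distribution;
#' `raw` correlates untransformed counts.
#'
#' @param ctss A `ctss_table` from [merge_samples()].
#' @param transform `"log1p"` (of TPM) or `"raw"` (counts).
#' @return A list of class `correlation_matrix`: `sample_ids`, symmetric
#'   matrix `r`, and the `transform` used. Samples with zero variance get
#'   `NA` correlations with a warning.
#' @export
pairwise_correlation <- function(ctss, transform = c("log1p", "raw")) {
  transform <- match.arg(transform)
  stopifnot(inherits(ctss, "ctss_table"), ncol(ctss$counts) >= 2L)
  x <- if (transform == "log1p") log1p(normalize_tpm(ctss)) else ctss$counts
  v <- apply(x, 2L, stats::var)
  r <- suppressWarnings(stats::cor(x, method = "pearson"))
  if (any(v == 0)) {
    warning("zero-variance sample(s): ",
            paste(colnames(x)[v == 0], collapse = ", "),
            "; correlations set to NA")
    r[v == 0, ] <- NA_real_
    r[, v == 0] <- NA_real_
  }
  diag(r) <- ifelse(v > 0, 1, NA_real_)
  structure(list(sample_ids = colnames(x), r = r, transform = transform),
            class = "correlation_matrix")
}

#' Summarise within-condition vs cross-condition correlations
#'
#' @param corr A `correlation_matrix`.
#' @param conditions Named vector mapping sample id to condition.
#' @return List with mean `replicate_r` (same condition) and `cross_r`
#'   (different conditions) over unordered pairs.
#' @export
correlation_summary <- function(corr, conditions) {
  ids <- corr$sample_ids
  cond <- conditions[ids]
  pairs <- which(upper.tri(corr$r), arr.ind = TRUE)
  same <- cond[pairs[, 1L]] == cond[pairs[, 2L]]
  vals <- corr$r[pairs]
  list(replicate_r = mean(vals[same], na.rm = TRUE),
       cross_r = mean(vals[!same], na.rm = TRUE),
       min_replicate_r = min(vals[same], na.rm = TRUE))
}
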