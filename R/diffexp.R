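# Count-based differential expression between two conditions:
# TMM normalization, conditional NB dispersion estimation, NB exact test,
# Benjamini-Hochberg FDR and the increased/decreased split.
#
# The negative-binomial variance model throughout is var = mu + phi * mu^2.

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' For each sample against a reference (the sample whose upper-quartile
#' relative expression is closest to the mean), gene-wise log2 ratios (M) and
#' average log2 abundances (A) are computed over rows nonzero in both
#' samples; the top/bottom 30% by M and 5% by A are trimmed; the factor is
#' 2 to the precision-weighted mean of the remaining M values. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Cluster x sample count matrix (>= 2 samples).
#' @param library_size Optional library sizes; default column sums.
#' @return List of class `norm_factors`: `factors` (geometric mean 1),
#'   `library_size`, `effective_library_size` and the reference sample id.
#' @export
tmm_factors <- function(counts, library_size = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2L)
  if (is.null(library_size)) library_size <- colSums(counts)
  if (any(library_size <= 0)) stop("sample with zero library size")
  f75 <- vapply(seq_len(ncol(counts)), function(s)
    quantile(counts[, s] / library_size[s], 0.75, names = FALSE), 0)
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(counts)), function(s)
    tmm_pair(counts[, s], counts[, ref], library_size[s], library_size[ref]),
    0)
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(counts)
  structure(list(factors = factors, library_size = library_size,
                 effective_library_size = library_size * factors,
                 reference = colnames(counts)[ref] %||% ref),
            class = "norm_factors")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-sample-vs-reference TMM factor (untrimmed weights follow the
# delta-method variance of M for binomial sampling)
tmm_pair <- function(y, yr, n, nr, trim_m = 0.3, trim_a = 0.05) {
  keep <- y > 0 & yr > 0
  if (!any(keep)) stop("no rows nonzero in both sample and reference")
  y <- y[keep]; yr <- yr[keep]
  p <- y / n; pr <- yr / nr
  M <- log2(p / pr)
  A <- (log2(p) + log2(pr)) / 2
  if (max(abs(M)) < 1e-6) return(1)
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  nn <- length(M)
  loM <- floor(nn * trim_m) + 1; hiM <- nn + 1 - loM
  loA <- floor(nn * trim_a) + 1; hiA <- nn + 1 - loA
  rM <- rank(M); rA <- rank(A)  # average ranks keep tied M values together
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  f <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

# --- quantile adjustment of counts to a common library size ------------------
# Interpolated quantile matching of NB CDFs: the mid-P cumulative probability
# of the observed count under NB(mean = rel_mu * lib_s, phi) is mapped through
# the quantile function of a moment-matched gamma at the common library size.
# The gamma gives a continuous interpolation of the discrete NB quantiles.
q2q_nb <- function(y, input_mean, output_mean, phi) {
  y <- as.numeric(y)
  out <- numeric(length(y))
  pos <- input_mean > 0
  if (!any(pos)) return(out)
  y <- y[pos]; mi <- input_mean[pos]; mo <- output_mean[pos]
  if (phi > 0) {
    size <- 1 / phi
    u <- stats::pnbinom(y - 1, mu = mi, size = size) +
      0.5 * stats::dnbinom(y, mu = mi, size = size)
  } else {
    u <- stats::ppois(y - 1, lambda = mi) + 0.5 * stats::dpois(y, lambda = mi)
  }
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  v <- mo + phi * mo^2
  shape <- mo^2 / v
  rate <- mo / v
  out[pos] <- stats::qgamma(u, shape = shape, rate = rate)
  out
}

# Equalize a count matrix to a common effective library size (geometric mean),
# returning pseudo-counts. rel_mu per row is estimated from group means.
equalize_lib_sizes <- function(counts, groups, eff_lib, phi) {
  counts <- as.matrix(counts)
  common <- exp(mean(log(eff_lib)))
  pseudo <- counts
  for (g in unique(groups)) {
    cols <- which(groups == g)
    rel <- rowSums(counts[, cols, drop = FALSE]) / sum(eff_lib[cols])
    for (s in cols) {
      pseudo[, s] <- q2q_nb(counts[, s], rel * eff_lib[s], rel * common, phi)
    }
  }
  list(pseudo = pseudo, common_lib = common)
}

#' Estimate the common NB dispersion by conditional maximum likelihood
#'
#' Counts are quantile-adjusted to a common effective library size, then the
#' dispersion phi maximizing the summed NB conditional log-likelihood
#' (conditioning on per-group row totals) is found by 1-D optimization on
#' `[1e-6, 10]`. The optional tagwise mode shrinks per-row CML estimates
#' toward the common value with `prior_df` weight.
#'
#' @param counts Cluster x sample count matrix.
#' @param groups Factor/character vector of group membership per sample.
#' @param norm Optional `norm_factors`; default TMM on `counts`.
#' @param tagwise Also compute shrunken per-row dispersions?
#' @param prior_df Shrinkage weight (equivalent rows of common-likelihood
#'   information) for the tagwise estimates.
#' @return List of class `dispersion_model`: `common_dispersion`, optional
#'   `tagwise_dispersion`, `prior_df`.
#' @export
estimate_common_dispersion <- function(counts, groups, norm = NULL,
                                       tagwise = FALSE, prior_df = 10) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(ncol(counts) == length(groups))
  if (max(table(groups)) < 2L) stop("need >= 2 replicates in >= 1 group")
  if (is.null(norm)) norm <- tmm_factors(counts)
  eff <- norm$effective_library_size
  if (all(apply(counts, 1L, function(r) all(r == r[1L])))) {
    warning("all rows constant; no overdispersion evidence, phi set to 1e-6")
    return(structure(list(common_dispersion = 1e-6,
                          tagwise_dispersion = NULL, prior_df = prior_df),
                     class = "dispersion_model"))
  }
  phi <- 0.1
  for (iter in 1:2) {
    eq <- equalize_lib_sizes(counts, groups, eff, phi)
    pseudo <- round(eq$pseudo)
    obj <- function(lphi) cml_loglik(pseudo, groups, exp(lphi))
    opt <- optimize(obj, interval = log(c(1e-6, 10)), maximum = TRUE,
                    tol = 1e-6)
    phi <- exp(opt$maximum)
  }
  tw <- NULL
  if (tagwise) {
    grid <- exp(seq(log(1e-6), log(10), length.out = 45L))
    L <- vapply(grid, function(p) cml_loglik_rows(pseudo, groups, p),
                numeric(nrow(pseudo)))  # rows x grid
    if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
    common_curve <- colMeans(L)
    tw <- grid[max.col(L + prior_df * rep(common_curve, each = nrow(L)),
                       ties.method = "first")]
    names(tw) <- rownames(counts)
  }
  structure(list(common_dispersion = phi, tagwise_dispersion = tw,
                 prior_df = prior_df),
            class = "dispersion_model")
}

# summed conditional log-likelihood over rows and groups at dispersion phi,
# assuming equalized library sizes; r = 1/phi
cml_loglik <- function(counts, groups, phi) {
  sum(cml_loglik_rows(counts, groups, phi))
}

cml_loglik_rows <- function(counts, groups, phi) {
  r <- 1 / phi
  ll <- numeric(nrow(counts))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    n <- length(cols)
    if (n < 2L) next
    y <- counts[, cols, drop = FALSE]
    z <- rowSums(y)
    ll <- ll + rowSums(lgamma(y + r)) + lgamma(n * r) -
      lgamma(z + n * r) - n * lgamma(r)
  }
  ll
}

#' Conditional negative-binomial exact test for one cluster
#'
#' Counts are quantile-adjusted to a common library size, then, conditional
#' on the total pseudo-count, the two-sided p-value is the sum of the
#' probabilities of all splits whose conditional probability is less than or
#' equal to that of the observed split. With group sums distributed
#' NB(n_g * mu, dispersion phi / n_g), the conditional split distribution is
#' negative hypergeometric (free of mu), and is enumerated directly; in the
#' phi -> 0 limit it is binomial.
#'
#' @param counts_a,counts_b Non-negative count vectors for the two groups.
#' @param phi NB dispersion (>= 0).
#' @param lib_a,lib_b Effective library sizes per sample; equal sizes skip
#'   the quantile adjustment.
#' @return Two-sided p-value in (0, 1].
#' @export
exact_test_nb <- function(counts_a, counts_b, phi,
                          lib_a = rep(1, length(counts_a)),
                          lib_b = rep(1, length(counts_b))) {
  stopifnot(all(counts_a >= 0), all(counts_b >= 0), phi >= 0)
  n1 <- length(counts_a); n2 <- length(counts_b)
  libs <- c(lib_a, lib_b)
  if (diff(range(libs)) / max(libs) > 1e-9) {
    y <- matrix(c(counts_a, counts_b), nrow = 1L)
    eq <- equalize_lib_sizes(y, rep(c("a", "b"), c(n1, n2)), libs, phi)
    s1 <- round(sum(eq$pseudo[1, seq_len(n1)]))
    s2 <- round(sum(eq$pseudo[1, n1 + seq_len(n2)]))
  } else {
    s1 <- sum(counts_a); s2 <- sum(counts_b)
  }
  nb_split_pvalue(s1, s2, n1, n2, phi)
}

# p-value for observed group sums s1, s2 with n1, n2 samples at dispersion phi
nb_split_pvalue <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  a <- split_range(t, n1, n2, phi)
  lw <- split_logweights(a, t, n1, n2, phi)
  lw <- lw - max(lw)
  w <- exp(lw)
  i_obs <- match(s1, a)
  if (is.na(i_obs)) return(min(1, 1e-12))  # observed outside truncation window
  p_obs <- w[i_obs]
  p <- sum(w[w <= p_obs * (1 + 1e-10)]) / sum(w)
  min(p, 1)
}

# unnormalized log conditional probabilities of splits (a, t - a)
split_logweights <- function(a, t, n1, n2, phi) {
  if (phi > 0) {
    r1 <- n1 / phi; r2 <- n2 / phi
    lgamma(a + r1) - lgamma(a + 1) + lgamma(t - a + r2) - lgamma(t - a + 1)
  } else {
    pi1 <- n1 / (n1 + n2)
    lchoose(t, a) + a * log(pi1) + (t - a) * log1p(-pi1)
  }
}

# enumeration range: exact below 1e5, truncated to >= 1 - 1e-12 mass above
split_range <- function(t, n1, n2, phi) {
  if (t <= 1e5) return(0:t)
  pi1 <- n1 / (n1 + n2)
  mu <- t * pi1
  v <- t * pi1 * (1 - pi1) * (1 + phi * t / (n1 + n2))
  half <- ceiling(8 * sqrt(v)) + 10
  max(0, floor(mu - half)):min(t, ceiling(mu + half))
}

#' Run the exact test across a count matrix
#'
#' @param counts Cluster x sample count matrix.
#' @param groups Two-level group vector (per column); the second level given
#'   by `contrast` is the numerator of the fold change.
#' @param dispersion A `dispersion_model` or a single phi value; tagwise
#'   dispersions are used when present.
#' @param norm Optional `norm_factors`; default TMM on `counts`.
#' @param contrast Character vector `c(reference, treatment)`.
#' @param pseudocount Added to each group-mean TPM before the log2 ratio.
#' @param alpha FDR threshold for the increased/decreased split.
#' @return `data.table` of class-tagged DE results: `cluster_id`, `log2fc`,
#'   `p_value`, `fdr`, `direction`, plus per-condition mean normalized TPM.
#' @export
de_table <- function(counts, groups, dispersion, norm = NULL,
                     contrast = c("control", "stimulated"),
                     pseudocount = 0.25, alpha = 0.1) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(all(groups %in% contrast), length(contrast) == 2L)
  if (is.null(norm)) norm <- tmm_factors(counts)
  phi_common <- if (inherits(dispersion, "dispersion_model"))
    dispersion$common_dispersion else dispersion
  phis <- rep(phi_common, nrow(counts))
  if (inherits(dispersion, "dispersion_model") &&
      !is.null(dispersion$tagwise_dispersion)) {
    phis <- dispersion$tagwise_dispersion
  }
  eff <- norm$effective_library_size
  ca <- which(groups == contrast[1L]); cb <- which(groups == contrast[2L])
  tpm <- normalize_tpm(counts, library_size = eff)
  mean_ref <- rowMeans(tpm[, ca, drop = FALSE])
  mean_trt <- rowMeans(tpm[, cb, drop = FALSE])
  log2fc <- log2((mean_trt + pseudocount) / (mean_ref + pseudocount))
  # equalize once per distinct phi set (common case: one phi for all rows)
  pv <- numeric(nrow(counts))
  for (phi in unique(phis)) {
    rows <- which(phis == phi)
    eq <- equalize_lib_sizes(counts[rows, , drop = FALSE], groups, eff, phi)
    ps <- round(eq$pseudo)
    s1 <- rowSums(ps[, ca, drop = FALSE])
    s2 <- rowSums(ps[, cb, drop = FALSE])
    pv[rows] <- vapply(seq_along(rows), function(i)
      nb_split_pvalue(s1[i], s2[i], length(ca), length(cb), phi), 0)
  }
  res <- data.table(
    cluster_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    log2fc = log2fc, p_value = pv, fdr = bh_fdr(pv),
    mean_tpm_control = mean_ref, mean_tpm_stimulated = mean_trt)
  res[, direction := classify_de(fdr, log2fc, alpha = alpha)]
  res[]
}

#' Benjamini-Hochberg step-up FDR
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, mapped back to input
#' order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q[order(o)]
}

#' Increased / decreased / unchanged partition of DE results
#'
#' Increased iff `fdr < alpha` and `log2fc > 0`; decreased iff `fdr < alpha`
#' and `log2fc < 0`; otherwise unchanged. A significant row with log2fc
#' exactly 0 is kept as unchanged (with a message).
#'
#' @param fdr,log2fc Vectors from the DE table.
#' @param alpha FDR threshold (default 0.1).
#' @return Character vector in `{increased, decreased, unchanged}`.
#' @export
classify_de <- function(fdr, log2fc, alpha = 0.1) {
  out <- rep("unchanged", length(fdr))
  out[fdr < alpha & log2fc > 0] <- "increased"
  out[fdr < alpha & log2fc < 0] <- "decreased"
  zero_sig <- fdr < alpha & log2fc == 0
  if (any(zero_sig)) {
    message(sum(zero_sig), " significant row(s) with zero fold change kept as unchanged")
  }
  out
}
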