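test_that("TMM factors: identity, geometric mean, scaled-sample recovery", {
  set.seed(31)
  y <- matrix(rnbinom(200 * 4, mu = exp(rnorm(200, log(80), 1)), size = 10),
              ncol = 4, dimnames = list(NULL, paste0("s", 1:4)))
  same <- cbind(y[, 1], y[, 1], y[, 1])
  colnames(same) <- paste0("r", 1:3)
  expect_equal(unname(tmm_factors(same)$factors), rep(1, 3))
  nf <- tmm_factors(y)
  expect_equal(exp(mean(log(nf$factors))), 1, tolerance = 1e-12)
  # a pure depth change with no differential rows: doubling one sample's
  # counts doubles its library size, so its TMM factor stays ~1
  y2 <- y
  y2[, 2] <- y[, 2] * 2L
  nf2 <- tmm_factors(y2)
  expect_equal(unname(nf2$factors[2] / nf2$factors[1]),
               unname(nf$factors[2] / nf$factors[1]), tolerance = 0.01)
  expect_equal(unname(nf2$effective_library_size[2] /
                        nf$effective_library_size[2]), 2, tolerance = 0.01)
})

test_that("TMM factors agree with an established reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(32)
  for (i in 1:3) {
    y <- matrix(rnbinom(500 * 6, mu = exp(rnorm(500, log(60), 1.2)),
                        size = 8), ncol = 6,
                dimnames = list(NULL, paste0("s", 1:6)))
    lib <- colSums(y)
    mine <- tmm_factors(y, lib)$factors
    ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = y, lib.size = lib),
                                  method = "TMM")$samples$norm.factors
    expect_equal(unname(mine), ref, tolerance = 1e-6)
  }
})

test_that("exact test reproduces closed-form and enumeration oracles", {
  # binomial limit: 0 vs 10 at phi -> 0 doubles the extreme tail
  expect_equal(exact_test_nb(0, 10, 0), 2 / 1024)
  # equal pseudo-counts: observed split is the mode
  expect_equal(exact_test_nb(c(5, 5), c(5, 5), 0.1), 1)
  # both groups all-zero
  expect_equal(exact_test_nb(c(0, 0), c(0, 0), 0.2), 1)
  # enumeration oracle at 5 vs 25, phi 0.1
  expect_equal(exact_test_nb(5, 25, 0.1), oracle_split_pvalue(5, 25, 1, 1, 0.1),
               tolerance = 1e-9)
  # replicated groups
  expect_equal(exact_test_nb(c(2, 3), c(10, 9), 0.05),
               oracle_split_pvalue(5, 19, 2, 2, 0.05), tolerance = 1e-9)
})

test_that("exact test is symmetric and monotone toward the expectation", {
  expect_equal(exact_test_nb(5, 25, 0.1), exact_test_nb(25, 5, 0.1))
  # moving the split toward the (equal) expectation never decreases p
  ps <- vapply(0:15, function(a) exact_test_nb(a, 30 - a, 0.1), 0)
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("quantile adjustment makes the test well-calibrated under unequal depth", {
  set.seed(33)
  # same relative abundance, 3x depth difference: p should not be extreme
  libs <- c(1e6, 1e6, 3e6, 3e6)
  mu <- 50 * libs / 1e6
  p <- replicate(200, {
    y <- rnbinom(4, mu = mu, size = 20)
    exact_test_nb(y[1:2], y[3:4], 0.05, libs[1:2], libs[3:4])
  })
  expect_gt(mean(p < 0.05), 0)  # sanity: not degenerate at 1
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("BH step-up matches the hand-computed example and edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(34)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  }
})

test_that("common dispersion recovery and degenerate inputs", {
  set.seed(35)
  mu <- exp(rnorm(800, log(50), 1))
  y <- matrix(rnbinom(800 * 8, mu = rep(mu, 8), size = 1 / 0.1), ncol = 8,
              dimnames = list(NULL, paste0("s", 1:8)))
  fit <- estimate_common_dispersion(y, rep(c("a", "b"), each = 4))
  expect_gt(fit$common_dispersion, 0.07)
  expect_lt(fit$common_dispersion, 0.13)
  # Poisson data: phi at (near) zero
  yp <- matrix(rpois(800 * 8, rep(mu, 8)), ncol = 8,
               dimnames = list(NULL, paste0("s", 1:8)))
  expect_lt(estimate_common_dispersion(yp,
                                       rep(c("a", "b"), each = 4))$common_dispersion,
            0.01)
  # constant rows: lower bound with warning
  flat <- matrix(5L, nrow = 3, ncol = 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_warning(f0 <- estimate_common_dispersion(flat, c("a", "a", "b", "b")),
                 "constant")
  expect_equal(f0$common_dispersion, 1e-6)
})

test_that("tagwise dispersions shrink toward the common value", {
  set.seed(36)
  mu <- exp(rnorm(400, log(60), 1))
  y <- matrix(rnbinom(400 * 8, mu = rep(mu, 8), size = 1 / 0.08), ncol = 8,
              dimnames = list(NULL, paste0("s", 1:8)))
  fit <- estimate_common_dispersion(y, rep(c("a", "b"), each = 4),
                                    tagwise = TRUE, prior_df = 10)
  expect_length(fit$tagwise_dispersion, 400)
  expect_lt(sd(log(fit$tagwise_dispersion)), 1.5)
  expect_equal(median(fit$tagwise_dispersion), fit$common_dispersion,
               tolerance = 0.5)
})

test_that("DE table symmetry: swapping groups negates log2FC, keeps p", {
  set.seed(37)
  y <- matrix(rnbinom(100 * 8, mu = exp(rnorm(100, log(50), 1)), size = 15),
              ncol = 8, dimnames = list(NULL, paste0("s", 1:8)))
  g <- rep(c("control", "stimulated"), each = 4)
  d1 <- de_table(y, g, 0.06)
  d2 <- de_table(y, rev(g), 0.06)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-9)
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-9)
})

test_that("classification rule partitions results at the FDR threshold", {
  expect_equal(classify_de(c(0.05, 0.05, 0.2), c(2, -2, 5)),
               c("increased", "decreased", "unchanged"))
  expect_message(out <- classify_de(0.01, 0), "zero fold")
  expect_equal(out, "unchanged")
})
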