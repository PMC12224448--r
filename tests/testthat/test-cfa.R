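sim_factor <- function(n, lam, seed, psi = 1 - lam^2) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    X <- sapply(seq_along(lam), function(j) {
      lam[j] * f + sqrt(psi[j]) * rnorm(n)
    })
    colnames(X) <- paste0("x", seq_along(lam))
    list(X = X, f = f)
  })
}

test_that("ML loadings recover the generating values", {
  lam <- c(0.7, 0.6, 0.5, 0.4)
  sim <- sim_factor(4000, lam, seed = 1)
  fit <- fit_cfa(sim$X)
  expect_lt(max(abs(fit$loadings - lam)), 0.05)
  expect_true(all(fit$uniquenesses > 0))
  expect_true(fit$fit_meta$converged)
  # implied covariance is positive definite
  Sigma <- tcrossprod(fit$loadings) + diag(fit$uniquenesses)
  expect_true(all(eigen(Sigma, only.values = TRUE)$values > 0))
})

test_that("the ML solution is stationary at the population covariance", {
  # a sample whose correlation matrix equals the implied Sigma exactly
  # should return the generating parameters (gradient ~ 0 at the truth)
  lam <- c(0.75, 0.65, 0.55, 0.45, 0.35)
  Sigma <- tcrossprod(lam) + diag(1 - lam^2)
  X <- MASS::mvrnorm(600, rep(0, 5), Sigma, empirical = TRUE)
  fit <- fit_cfa(X)
  expect_lt(max(abs(fit$loadings - lam)), 1e-3)
  expect_lt(fit$fit_meta$grad_norm, 1e-4)
})

test_that("independent indicators yield near-zero loadings", {
  withr::with_seed(3, X <- matrix(rnorm(3000 * 4), ncol = 4))
  fit <- suppressWarnings(fit_cfa(X))
  # a one-factor ML fit latches onto the largest chance correlation
  # (~1/sqrt(n)), so loadings shrink like n^(-1/4)
  expect_lt(max(abs(fit$loadings)), 0.25)
  implied_cor <- tcrossprod(fit$loadings)
  expect_lt(max(abs(implied_cor[upper.tri(implied_cor)])), 0.04)
})

test_that("equal cognitive loadings of 0.65 give inter-test correlations near 0.42", {
  sp <- lean_spec(8000, seed = 4,
                  cog_loadings = c(vnr = 0.65, vismem = 0.65, rt = 0.65,
                                   prosmem = 0.65))
  co <- transform_cognitive(generate_cohort(sp)$cohort)
  d <- cohort_data(co)
  # the linearly generated tests (vnr, prosmem, log-RT) carry lambda_i *
  # lambda_j = 0.4225 intercorrelations; log-RT is negatively oriented
  expect_lt(abs(cor(d$cog_vnr, d$cog_prosmem) - 0.4225), 0.05)
  expect_lt(abs(abs(cor(d$cog_vnr, d$cog_rt)) - 0.4225), 0.05)
  expect_lt(abs(abs(cor(d$cog_prosmem, d$cog_rt)) - 0.4225), 0.05)
})

test_that("factor scores approach the determinacy bound", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  sim <- sim_factor(4000, lam, seed = 5)
  fit <- fit_cfa(sim$X)
  s <- cfa_scores(fit, sim$X)
  expect_equal(mean(s), 0, tolerance = 1e-10)
  expect_equal(sd(s), 1, tolerance = 1e-10)
  expect_gte(cor(s, sim$f), fit$determinacy - 0.05)
})

test_that("score extraction validates columns and degenerate models", {
  sim <- sim_factor(500, c(0.7, 0.6, 0.5), seed = 6)
  fit <- fit_cfa(sim$X)
  Xbad <- sim$X
  colnames(Xbad) <- c("a", "b", "c")
  expect_error(cfa_scores(fit, Xbad), "do not match")
  degen <- fit
  degen$loadings[] <- 0
  degen$score_weights[] <- 0
  expect_error(cfa_scores(degen, sim$X), "degenerate")
  # limit case: one indicator with loading 1 reduces the score to the
  # standardized indicator itself
  one <- structure(list(kind = "cfa", indicator_names = "x1",
                        loadings = c(x1 = 1), score_weights = 1),
                   class = "latent_model")
  x <- rnorm(50)
  expect_equal(cfa_scores(one, matrix(x, dimnames = list(NULL, "x1"))),
               (x - mean(x)) / sd(x), tolerance = 1e-12)
})

test_that("ill-posed CFA inputs are rejected", {
  expect_error(fit_cfa(matrix(rnorm(20), ncol = 2)), "at least 3")
  expect_error(fit_cfa(matrix(rnorm(12), ncol = 4)), "too few rows")
})
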