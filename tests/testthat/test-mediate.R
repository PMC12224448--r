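random_med_data <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(x = rnorm(n), m1 = rnorm(n), m2 = rnorm(n), y = rnorm(n),
               age = runif(n, 45, 80), sex = rbinom(n, 1, 0.5))
  })
}

test_that("difference-in-coefficients equals the path products exactly", {
  d <- random_med_data(300, 61)
  for (topo in c("single", "parallel", "sequential")) {
    meds <- if (topo == "single") "m1" else c("m1", "m2")
    fit <- fit_mediation(d, "x", "y", meds, topology = topo)
    expect_lt(abs(fit$identity_gap), 1e-10)
  }
})

test_that("the crossprod engine reproduces independent lm fits", {
  d <- random_med_data(250, 62)
  fit <- fit_mediation(d, "x", "y", c("m1", "m2"),
                       topology = "sequential")
  c_total <- coef(lm(y ~ x + age + sex, d))[["x"]]
  a <- coef(lm(m1 ~ x + age + sex, d))[["x"]]
  m2fit <- lm(m2 ~ x + m1 + age + sex, d)
  outfit <- lm(y ~ x + m1 + m2 + age + sex, d)
  expect_equal(fit$paths[["c_total"]], c_total, tolerance = 1e-10)
  expect_equal(fit$paths[["a"]], a, tolerance = 1e-10)
  expect_equal(fit$paths[["a2"]], coef(m2fit)[["x"]], tolerance = 1e-10)
  expect_equal(fit$paths[["d21"]], coef(m2fit)[["m1"]], tolerance = 1e-10)
  expect_equal(fit$paths[["c_prime"]], coef(outfit)[["x"]],
               tolerance = 1e-10)
  expect_equal(fit$paths[["b1"]], coef(outfit)[["m1"]], tolerance = 1e-10)
  expect_equal(fit$paths[["b2"]], coef(outfit)[["m2"]], tolerance = 1e-10)
  # OLS standard error of the direct effect agrees with lm
  expect_equal(fit$path_se[["c_prime"]],
               summary(outfit)$coefficients["x", "Std. Error"],
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected; near-degenerate shrink the CI", {
  d <- random_med_data(200, 63)
  d$m1 <- d$x
  expect_error(fit_mediation(d, "x", "y", "m1"), "rank-deficient")
  d$m1 <- d$x + 1e-5 * rnorm(200)
  b <- bootstrap_mediation(d, "x", "y", "m1", n_boot = 200, seed = 1)
  ci_a <- b$boot$ci["a", ]
  expect_lt(ci_a[["upper"]] - ci_a[["lower"]], 1e-2)
})

test_that("mediator/covariate overlap and topology mismatches error", {
  d <- random_med_data(100, 64)
  expect_error(fit_mediation(d, "x", "y", "x"), "distinct")
  expect_error(fit_mediation(d, "x", "y", "m1", topology = "sequential"),
               "two mediators")
  expect_error(fit_mediation(d, "x", "y", c("m1", "m2"),
                             topology = "single"), "one mediator")
  expect_error(bootstrap_mediation(d, "x", "y", "m1", n_boot = 50),
               "at least 200")
})

test_that("percent mediated is undefined when the total effect vanishes", {
  d <- random_med_data(300, 65)
  d$y <- resid(lm(y ~ x, d))  # exactly orthogonal to x
  fit <- fit_mediation(d, "x", "y", "m1", covariates = character(0))
  expect_true(is.na(fit$percent_mediated))
})

test_that("percent mediated is invariant to positive rescaling", {
  sp <- lean_spec(2000, 66, a = -0.5, b1 = 0.1, c_dir = 0.02)
  d <- med_frame(generate_cohort(sp))
  f0 <- fit_mediation(d, "x", "y", "m1")
  d2 <- transform(d, x = 3.2 * x, m1 = 0.05 * m1, y = 17 * y)
  f2 <- fit_mediation(d2, "x", "y", "m1")
  expect_equal(f2$percent_mediated, f0$percent_mediated,
               tolerance = 1e-10)
})

test_that("bootstrap CIs are seed-reproducible and centred on the fit", {
  sp <- lean_spec(1000, 67, a = -0.5, b1 = 0.15)
  d <- med_frame(generate_cohort(sp))
  b1 <- bootstrap_mediation(d, "x", "y", "m1", n_boot = 300, seed = 9)
  b2 <- bootstrap_mediation(d, "x", "y", "m1", n_boot = 300, seed = 9)
  expect_identical(b1$boot$ci, b2$boot$ci)
  b3 <- bootstrap_mediation(d, "x", "y", "m1", n_boot = 300, seed = 10)
  expect_false(identical(b1$boot$ci, b3$boot$ci))
  ci <- b1$boot$ci
  for (q in c("a", "b1", "c_prime", "indirect_total")) {
    est <- if (q == "indirect_total") b1$indirect_total else b1$paths[[q]]
    expect_gte(est, ci[q, "lower"])
    expect_lte(est, ci[q, "upper"])
  }
})

test_that("paths are recovered without bias across a small spec grid", {
  grid <- list(c(a = -0.55, b1 = 0.078, c = 0),
               c(a = -0.3, b1 = 0.2, c = 0.05),
               c(a = 0.4, b1 = -0.15, c = -0.02))
  for (g in grid) {
    ests <- t(sapply(1:25, function(r) {
      sp <- lean_spec(3000, 700 + r, a = g[["a"]], b1 = g[["b1"]],
                      c_dir = g[["c"]])
      d <- med_frame(generate_cohort(sp))
      f <- fit_mediation(d, "x", "y", "m1", covariates = character(0))
      c(f$paths[["a"]], f$paths[["b1"]], f$paths[["c_prime"]])
    }))
    mc_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
    bias <- colMeans(ests) - c(g[["a"]], g[["b1"]], g[["c"]])
    expect_true(all(abs(bias) <= 3 * mc_se + 1e-3))
  }
})

test_that("campaigns produce one labelled row per model with family FDR", {
  sp <- synth_spec(n_subjects = 800, seed = 68)
  out <- generate_cohort(sp)
  co <- complete_case_filter(
    aggregate_vrf_count(transform_cognitive(out$cohort)))$cohort
  lat <- derive_latents(co, max_pcs = 3, max_modes = 3, min_pcs = 2,
                        seed = 68)
  d <- cbind(as.data.frame(lat$scores),
             cohort_data(co)[, c("age", "sex")])
  meds <- intersect(c("heart_pc1", "heart_pc2", "gmv", "gFA"), names(d))
  tab <- run_campaign(d, "latent_single", mediators = meds,
                      n_boot = 200, seed = 68)
  expect_identical(nrow(tab), length(meds))
  expect_setequal(tab$mediator, meds)
  expect_true(all(diff(tab$indirect) >= 0))  # sorted by indirect
  expect_true(all(tab$q >= tab$p - 1e-12))
  multi <- run_campaign(d, "latent_multiple", m1 = meds[1],
                        mediators = c("gmv", "gFA"), n_boot = 200,
                        seed = 69)
  expect_identical(nrow(multi), 4L)  # 2 mediators x 2 topologies
  expect_setequal(unique(multi$topology), c("parallel", "sequential"))
  expect_error(run_campaign(d, "no_such_campaign"), "arg")
})

test_that("feature and VRF-pair campaigns run on prepared columns", {
  sp <- lean_spec(600, 70, a = -0.5, b1 = 0.15)
  out <- generate_cohort(sp)
  co <- complete_case_filter(transform_cognitive(out$cohort))$cohort
  d <- cohort_data(co)
  tr <- out$truth$latents
  d$gVRF <- scale(tr$gvrf)[, 1]
  d$g <- scale(tr$g)[, 1]
  feats <- grep("^hrt_", names(d), value = TRUE)
  tab <- run_campaign(d, "individual_features", mediators = feats,
                      n_boot = 200, seed = 70)
  expect_identical(nrow(tab), length(feats))
  pairs <- run_campaign(d, "vrf_exam_pairs",
                        vrfs = c("vrf_bmi", "vrf_htn"),
                        exams = "cog_vnr", mediators = "gVRF",
                        n_boot = 200, seed = 71)
  expect_identical(nrow(pairs), 2L)
  expect_setequal(pairs$exposure, c("vrf_bmi", "vrf_htn"))
})
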