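test_that("identical spec and seed give byte-identical cohorts", {
  sp <- lean_spec(300, seed = 11, a = -0.4, b1 = 0.2)
  o1 <- generate_cohort(sp)
  o2 <- generate_cohort(sp)
  expect_identical(cohort_data(o1$cohort), cohort_data(o2$cohort))
  expect_identical(o1$truth$latents, o2$truth$latents)
  o3 <- generate_cohort(lean_spec(300, seed = 12, a = -0.4, b1 = 0.2))
  expect_false(identical(cohort_data(o1$cohort), cohort_data(o3$cohort)))
})

test_that("invalid specs are rejected", {
  expect_error(synth_spec(n_subjects = 0), "positive")
  expect_error(synth_spec(n_subjects = 5), "twice the number of latents")
  expect_error(lean_spec(300, 1, axes = list(list(heart = "intensity",
                                                  brain = "vol", r = 1.2))),
               "\\[0, 1\\)")
  # a target below 1 can still be unrealizable after determinacy inflation
  expect_error(lean_spec(300, 1, axes = list(list(heart = "intensity",
                                                  brain = "vol",
                                                  r = 0.97))),
               "not realizable")
  bad_heart <- list(intensity = c(i1 = 1.2, i2 = 0.5, i3 = 0.5))
  expect_error(lean_spec(300, 1, heart = bad_heart), "inside \\(-1, 1\\)")
})

test_that("with all structural paths zero, gVRF and g are independent", {
  n <- 20000
  out <- generate_cohort(lean_spec(n, seed = 21))
  r <- cor(out$truth$latents$gvrf, out$truth$latents$g)
  expect_lt(abs(r), 3 / sqrt(n))
})

test_that("implied effects follow the path-tracing closed form", {
  expect_equal(unname(implied_effects(lean_spec(100, 1))),
               c(0, 0, 0, 0))
  sp <- lean_spec(100, 1, a = 0.5, d = 0.4, b2 = 0.1)
  eff <- implied_effects(sp)
  expect_equal(unname(eff["indirect_heart_brain"]), 0.5 * 0.4 * 0.1)
  expect_equal(unname(eff["total"]),
               unname(eff["direct"] + eff["indirect_heart"] +
                        eff["indirect_heart_brain"]))
  # random paths: total always equals direct + all indirects
  withr::with_seed(9, {
    for (i in 1:10) {
      ps <- runif(5, -0.3, 0.3)
      sp <- lean_spec(100, i, a = ps[1], d = ps[2], b1 = ps[3],
                      b2 = ps[4], c_dir = ps[5])
      eff <- implied_effects(sp)
      expect_equal(unname(eff["total"]), unname(sum(eff[1:3])))
    }
  })
})

test_that("regression on generated latents recovers the implied total", {
  sp <- lean_spec(50000, seed = 31, a = -0.55, b1 = 0.078)
  eff <- implied_effects(sp)
  expect_equal(unname(eff["total"]), -0.0429)
  lat <- generate_cohort(sp)$truth$latents
  beta <- unname(coef(lm(lat$g ~ lat$gvrf))[2])
  expect_lt(abs(beta - eff[["total"]]), 0.01)
})

test_that("binary prevalence matches the liability threshold", {
  n <- 20000
  d <- cohort_data(generate_cohort(lean_spec(n, seed = 41))$cohort)
  thr <- synth_spec()$binary_thresholds
  for (b in names(thr)) {
    p <- 1 - pnorm(thr[[b]])
    mc_se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(d[[paste0("vrf_", b)]]) - p), 2.5 * mc_se)
  }
})

test_that("feature covariance converges to the implied loadings structure", {
  lam <- c(i1 = 0.8, i2 = 0.75, i3 = 0.7, i4 = 0.6, i5 = 0.5)
  sp <- lean_spec(20000, seed = 51, heart = list(intensity = lam))
  d <- cohort_data(generate_cohort(sp)$cohort)
  X <- scale(as.matrix(d[, paste0("hrt_", names(lam))]))
  implied <- tcrossprod(lam) + diag(1 - lam^2)
  expect_lt(max(abs(cov(X) - implied)), 0.05)
})

test_that("shared axes reproduce the target cross-block correlation", {
  sp <- lean_spec(10000, seed = 61,
                  heart = list(size = c(s1 = .8, s2 = .8, s3 = .75,
                                        s4 = .75, s5 = .7)),
                  brain = list(vol = c(v1 = .8, v2 = .8, v3 = .75,
                                       v4 = .75, v5 = .7)),
                  axes = list(list(heart = "size", brain = "vol",
                                   r = 0.6)))
  d <- cohort_data(generate_cohort(sp)$cohort)
  cc <- cancor(scale(as.matrix(d[, grep("^hrt_", names(d))])),
               scale(as.matrix(d[, grep("^brn_", names(d))])))
  expect_lt(abs(cc$cor[1] - 0.6), 0.05)
})

test_that("missingness injection is binomial, seeded, and validated", {
  out <- generate_cohort(lean_spec(1000, seed = 71))
  co <- out$cohort
  expect_identical(inject_missingness(co, 0), co)
  expect_error(inject_missingness(co, 1.2), "\\[0, 1\\)")
  m1 <- inject_missingness(co, 0.1, seed = 5)
  m2 <- inject_missingness(co, 0.1, seed = 5)
  expect_identical(cohort_data(m1), cohort_data(m2))
  dict <- dictionary(co)
  target_cols <- dict$column[!dict$role %in% c("covariate", "confounder")]
  n_cells <- 1000 * length(target_cols)
  n_miss <- sum(is.na(cohort_data(m1)[, target_cols]))
  expect_lt(abs(n_miss - 0.1 * n_cells),
            3.5 * sqrt(n_cells * 0.1 * 0.9))
  # covariates and confounders are never blanked
  expect_false(anyNA(cohort_data(m1)[, c("age", "sex", "head_size",
                                         "bsa")]))
})
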