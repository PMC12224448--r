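rt_cohort <- function(rt, vismem) {
  n <- length(rt)
  mini_cohort(data.frame(subject_id = paste0("s", seq_len(n)),
                         rt = rt, vismem = vismem),
              roles = c("cognitive", "cognitive"),
              transforms = c("ln", "ln1p"))
}

test_that("cognitive transforms apply the documented log identities", {
  co <- rt_cohort(c(1, exp(2)), c(0, exp(1) - 1))
  out <- cohort_data(transform_cognitive(co))
  expect_equal(out$rt, c(0, 2))
  expect_equal(out$vismem, c(0, 1))
  expect_match(provenance(transform_cognitive(co)), "ln", all = FALSE)
})

test_that("cognitive transforms reject out-of-domain values by subject", {
  expect_error(transform_cognitive(rt_cohort(c(1, 0), c(0, 0))), "s2")
  expect_error(transform_cognitive(rt_cohort(c(1, 1), c(-0.5, 0))), "s1")
})

test_that("VRF count applies the published cutoffs with strict inequalities", {
  df <- data.frame(
    subject_id = c("low", "high", "boundary"),
    vrf_htn = c(0, 1, 0), vrf_diab = c(0, 1, 0), vrf_chol = c(0, 1, 0),
    vrf_pack_years = c(0, 10, 0),
    vrf_bmi = c(24, 30, 25.0),
    vrf_whr = c(0.80, 0.95, 0.85),
    sex = c(1, 0, 1), stringsAsFactors = FALSE)
  co <- mini_cohort(df, roles = c(rep("vrf_binary", 3),
                                  rep("vrf_continuous", 3), "covariate"))
  counts <- cohort_data(aggregate_vrf_count(co))$vrf_count
  expect_identical(counts, c(0L, 6L, 0L))
  # male at WHR 0.90 is also not high (strict >)
  df$sex <- c(0, 0, 0); df$vrf_whr <- c(0.80, 0.95, 0.90)
  co <- mini_cohort(df, roles = c(rep("vrf_binary", 3),
                                  rep("vrf_continuous", 3), "covariate"))
  expect_identical(cohort_data(aggregate_vrf_count(co))$vrf_count[3], 0L)
})

test_that("VRF count is monotone in each criterion and NA-propagating", {
  base <- data.frame(subject_id = "s1", vrf_htn = 0, vrf_diab = 0,
                     vrf_chol = 0, vrf_pack_years = 0, vrf_bmi = 24,
                     vrf_whr = 0.8, sex = 1)
  roles <- c(rep("vrf_binary", 3), rep("vrf_continuous", 3), "covariate")
  count_of <- function(df) {
    cohort_data(aggregate_vrf_count(mini_cohort(df, roles)))$vrf_count
  }
  flips <- list(vrf_htn = 1, vrf_diab = 1, vrf_chol = 1,
                vrf_pack_years = 5, vrf_bmi = 26, vrf_whr = 0.9)
  c0 <- count_of(base)
  for (nm in names(flips)) {
    df <- base; df[[nm]] <- flips[[nm]]
    expect_gte(count_of(df), c0)
  }
  df <- base; df$vrf_bmi <- NA
  expect_true(is.na(count_of(df)))
})

test_that("complete-case filter matches a brute-force row scan", {
  out <- generate_cohort(lean_spec(1000, seed = 81))
  co <- inject_missingness(out$cohort, 0.05, seed = 3)
  res <- complete_case_filter(co)
  dict <- dictionary(co)
  required <- dict$column
  brute_keep <- complete.cases(cohort_data(co)[, required])
  expect_identical(nrow(cohort_data(res$cohort)), sum(brute_keep))
  expect_identical(cohort_data(res$cohort)$subject_id,
                   cohort_data(co)$subject_id[brute_keep])
  rep <- res$report
  expect_equal(rep$n_input - rep$n_final, sum(rep$dropped_reasons))
  expect_true(all(diff(c(rep$n_input, rep$n_after_each_step)) <= 0))
})

test_that("filtering a complete table is the identity", {
  out <- generate_cohort(lean_spec(200, seed = 82))
  res <- complete_case_filter(out$cohort)
  expect_identical(cohort_data(res$cohort), cohort_data(out$cohort))
  expect_equal(sum(res$report$dropped_reasons), 0)
})

test_that("z-scoring uses the n-1 denominator and a train/apply contract", {
  df <- data.frame(subject_id = c("a", "b", "c"), v = c(1, 2, 3),
                   w = c(5, 5, 5))
  co <- mini_cohort(df, roles = c("heart_feature", "heart_feature"))
  z <- zscore_columns(co, "v")
  expect_equal(cohort_data(z$cohort)$v, c(-1, 0, 1))
  expect_equal(z$stats$sd, 1)
  expect_error(zscore_columns(co, "w"), "zero-variance.*w")
  # stored stats applied to new data need not recentre it
  df2 <- data.frame(subject_id = "d", v = 10, w = 1)
  new <- zscore_columns(mini_cohort(df2, roles = c("heart_feature",
                                                   "heart_feature")),
                        "v", stats = z$stats)
  expect_equal(cohort_data(new$cohort)$v, (10 - 2) / 1)
})

test_that("the provenance log is append-only and replayable", {
  out <- generate_cohort(lean_spec(300, seed = 83))
  raw <- out$cohort
  prepared <- transform_cognitive(raw)
  expect_true(all(provenance(raw) %in% provenance(prepared)))
  expect_gt(length(provenance(prepared)), length(provenance(raw)))
  expect_true(replay_transforms(raw, prepared))
})
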