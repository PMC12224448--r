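test_that("propensity model behaves on unconfounded and monotone cases", {
  withr::with_seed(51, {
    d <- data.frame(subject_id = paste0("s", 1:2000),
                    exposed = rbinom(2000, 1, 0.3),
                    age = rnorm(2000), sex = rbinom(2000, 1, 0.5))
  })
  ps <- estimate_propensity(d, "exposed", "age")
  expect_lt(abs(mean(ps$propensity) - mean(d$exposed)), 0.02)
  expect_lt(diff(range(ps$propensity)), 0.15)
  # strongly confounded exposure: probabilities monotone in the covariate
  withr::with_seed(52, {
    z <- rnorm(2000)
    e <- rbinom(2000, 1, plogis(-0.5 + 1.2 * z))
    d2 <- data.frame(subject_id = paste0("s", 1:2000), exposed = e, z = z)
  })
  ps2 <- estimate_propensity(d2, "exposed", "z")
  expect_true(all(diff(ps2$propensity[order(d2$z)]) >= -1e-12))
  # generating log-odds slope recovered
  expect_lt(abs(coef(ps2$model)["z"] - 1.2), 0.15)
})

test_that("perfect separation is rejected with advice", {
  d <- data.frame(subject_id = paste0("s", 1:100), z = 1:100,
                  exposed = as.integer(1:100 > 50))
  expect_error(estimate_propensity(d, "exposed", "z"), "separation")
})

test_that("an identical-covariate same-sex control is matched at distance 0", {
  d <- data.frame(subject_id = c("e1", "c1", "c2"),
                  exposed = c(1, 0, 0), sex = c(1, 1, 1))
  pr <- c(0.6, 0.6, 0.1)
  mp <- match_nearest(d, "exposed", pr)
  expect_identical(mp$pairs$control_id, "c1")
  expect_equal(mp$pairs$propensity_exposed - mp$pairs$propensity_control, 0)
})

test_that("sex is matched exactly or not at all", {
  d <- data.frame(subject_id = c("e1", "e2", "c1", "c2"),
                  exposed = c(1, 1, 0, 0), sex = c(1, 1, 0, 0))
  mp <- match_nearest(d, "exposed", c(0.5, 0.6, 0.5, 0.6))
  expect_identical(nrow(mp$pairs), 0L)
  expect_setequal(mp$unmatched, c("e1", "e2"))
})

test_that("matching is invariant to input row order", {
  withr::with_seed(53, {
    n <- 400
    d <- data.frame(subject_id = sprintf("s%03d", 1:n),
                    exposed = rbinom(n, 1, 0.3),
                    sex = rbinom(n, 1, 0.5), z = rnorm(n))
  })
  ps <- estimate_propensity(d, "exposed", "z")$propensity
  mp1 <- match_nearest(d, "exposed", ps)
  perm <- sample(n)
  mp2 <- match_nearest(d[perm, ], "exposed", ps[perm])
  o1 <- mp1$pairs[order(mp1$pairs$exposed_id), ]
  o2 <- mp2$pairs[order(mp2$pairs$exposed_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("matching improves covariate balance under confounding", {
  withr::with_seed(54, {
    n <- 3000
    age <- rnorm(n)
    e <- rbinom(n, 1, plogis(-1.2 + 0.9 * age))
    d <- data.frame(subject_id = sprintf("s%04d", 1:n), exposed = e,
                    sex = rbinom(n, 1, 0.5), age = age)
  })
  ps <- estimate_propensity(d, "exposed", "age")
  mp <- match_nearest(d, "exposed", ps$propensity,
                      balance_covariates = "age")
  expect_lt(abs(mp$balance$smd_after), abs(mp$balance$smd_before))
})

test_that("group contrasts report native-unit and percent differences", {
  withr::with_seed(55, {
    n <- 200
    noise <- rnorm(n); noise <- noise - mean(noise)
    d <- data.frame(subject_id = c(sprintf("e%03d", 1:n),
                                   sprintf("c%03d", 1:n)),
                    lvedv = c(144.81 + noise, 157.90 + noise),
                    same = rep(rnorm(n), 2))
  })
  mp <- structure(list(pairs = data.frame(
    exposed_id = sprintf("e%03d", 1:200),
    control_id = sprintf("c%03d", 1:200),
    propensity_exposed = 0.5, propensity_control = 0.5)),
    class = "matched_pairs")
  cmp <- paired_compare(d, mp, c("lvedv", "same"))
  row <- cmp[cmp$outcome == "lvedv", ]
  expect_equal(row$diff, -13.09, tolerance = 1e-10)
  expect_equal(row$pct_diff, 100 * (-13.09) / 157.90, tolerance = 1e-10)
  expect_equal(round(row$pct_diff, 2), -8.29)
  ident <- cmp[cmp$outcome == "same", ]
  expect_equal(ident$diff, 0)
  expect_equal(ident$p, 1)
})

test_that("a 0.3 SD effect over 400 pairs is detected after FDR", {
  withr::with_seed(56, {
    n <- 400
    d <- data.frame(subject_id = c(sprintf("e%03d", 1:n),
                                   sprintf("c%03d", 1:n)),
                    hit = c(rnorm(n, -0.3), rnorm(n, 0)),
                    null1 = rnorm(2 * n), null2 = rnorm(2 * n))
  })
  mp <- structure(list(pairs = data.frame(
    exposed_id = sprintf("e%03d", 1:400),
    control_id = sprintf("c%03d", 1:400),
    propensity_exposed = 0.5, propensity_control = 0.5)),
    class = "matched_pairs")
  cmp <- paired_compare(d, mp, c("hit", "null1", "null2"))
  expect_lt(cmp$q[cmp$outcome == "hit"], 0.05)
  expect_error(paired_compare(d, structure(list(pairs = mp$pairs[0, ]),
                                           class = "matched_pairs"),
                              "hit"),
               "no matched pairs")
})
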