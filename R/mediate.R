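# --- sufficient-statistics OLS engine ---------------------------------
#
# All mediation regressions are plain OLS with a shared covariate set, so
# every fit (and every bootstrap refit) can be computed from the
# cross-product matrix G = Z'WZ of the assembled design
# Z = [1, covs, x, m1, m2, y]. A bootstrap replicate is a multinomial
# weight vector, making replicates O(n * ncol^2) with no row copying.

ols_beta <- function(G, pred, resp, n = NULL, want_se = FALSE) {
  A <- G[pred, pred, drop = FALSE]
  b <- G[pred, resp]
  beta <- tryCatch(solve(A, b), error = function(e) {
    stop("rank-deficient design (predictors: ",
         paste(pred, collapse = ", "), ")", call. = FALSE)
  })
  out <- list(beta = stats::setNames(as.numeric(beta), pred))
  if (want_se) {
    rss <- max(0, G[resp, resp] - sum(beta * b))
    df <- n - length(pred)
    sigma2 <- rss / df
    out$se <- stats::setNames(sqrt(pmax(0, diag(solve(A)) * sigma2)), pred)
    out$df <- df
  }
  out
}

# Point estimates of every mediation quantity from a cross-product matrix.
med_quantities <- function(G, x, y, m1, m2, covs, topology,
                           n = NULL, want_se = FALSE) {
  base <- c("(Intercept)", covs)
  q <- list()
  tot <- ols_beta(G, c(base, x), y, n, want_se)
  a_fit <- ols_beta(G, c(base, x), m1, n, want_se)
  paths <- c(c_total = unname(tot$beta[x]), a = unname(a_fit$beta[x]))
  ses <- c(c_total = if (want_se) unname(tot$se[x]) else NA_real_,
           a = if (want_se) unname(a_fit$se[x]) else NA_real_)
  if (topology == "single") {
    out_fit <- ols_beta(G, c(base, x, m1), y, n, want_se)
    paths <- c(paths, c_prime = unname(out_fit$beta[x]),
               b1 = unname(out_fit$beta[m1]))
    if (want_se) ses <- c(ses, c_prime = unname(out_fit$se[x]),
                          b1 = unname(out_fit$se[m1]))
    indirect <- c(ind_m1 = unname(paths["a"] * paths["b1"]))
  } else {
    if (topology == "parallel") {
      m2_fit <- ols_beta(G, c(base, x), m2, n, want_se)
      paths <- c(paths, a2 = unname(m2_fit$beta[x]), d21 = 0)
      if (want_se) ses <- c(ses, a2 = unname(m2_fit$se[x]), d21 = NA_real_)
    } else {  # sequential: m2 ~ x + m1 + covs
      m2_fit <- ols_beta(G, c(base, x, m1), m2, n, want_se)
      paths <- c(paths, a2 = unname(m2_fit$beta[x]),
                 d21 = unname(m2_fit$beta[m1]))
      if (want_se) ses <- c(ses, a2 = unname(m2_fit$se[x]),
                            d21 = unname(m2_fit$se[m1]))
    }
    out_fit <- ols_beta(G, c(base, x, m1, m2), y, n, want_se)
    paths <- c(paths, c_prime = unname(out_fit$beta[x]),
               b1 = unname(out_fit$beta[m1]), b2 = unname(out_fit$beta[m2]))
    if (want_se) ses <- c(ses, c_prime = unname(out_fit$se[x]),
                          b1 = unname(out_fit$se[m1]),
                          b2 = unname(out_fit$se[m2]))
    indirect <- c(ind_m1 = unname(paths["a"] * paths["b1"]),
                  ind_m2 = unname(paths["a2"] * paths["b2"]))
    if (topology == "sequential") {
      indirect <- c(indirect,
                    ind_m1_m2 = unname(paths["a"] * paths["d21"] *
                                         paths["b2"]))
    }
  }
  ind_total <- sum(indirect)
  c_total <- paths[["c_total"]]
  percent <- if (abs(c_total) <
                 10 * .Machine$double.eps * max(1, abs(paths["c_prime"]))) {
    NA_real_
  } else {
    100 * (c_total - paths[["c_prime"]]) / c_total
  }
  list(paths = paths, ses = ses, indirect = indirect,
       indirect_total = ind_total, percent_mediated = percent,
       identity_gap = c_total - paths[["c_prime"]] - ind_total)
}

flatten_quantities <- function(q) {
  c(q$paths, q$indirect, indirect_total = q$indirect_total,
    percent_mediated = q$percent_mediated)
}

build_design <- function(data, x, y, mediators, covariates) {
  cols <- c(x, mediators, covariates, y)
  assert_cols(data, cols)
  if (anyNA(data[, cols])) {
    stop("mediation requires complete cases on x, y, mediators and ",
         "covariates", call. = FALSE)
  }
  Z <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(lapply(data[, cols, drop = FALSE],
                                            as.numeric))))
  colnames(Z) <- c("(Intercept)", cols)
  Z
}

#' Fit a single, parallel, or sequential mediation model
#'
#' All equations are OLS regressions sharing the covariate set
#' (age and sex by default, plus any extra controls):
#'
#' * total:     `y ~ x + covs` giving the total effect `c_total`;
#' * mediator:  `m1 ~ x + covs` giving `a`;
#' * parallel adds `m2 ~ x + covs` (`a2`), sequential instead
#'   `m2 ~ x + m1 + covs` (`a2`, `d21`);
#' * outcome:   `y ~ x + m1 (+ m2) + covs` giving the direct effect
#'   `c_prime` and `b1` (`b2`).
#'
#' Indirect effects are path products (`a*b1`, `a2*b2`, and sequentially
#' `a*d21*b2`); because every equation is OLS on identical covariates,
#' the difference in coefficients `c_total - c_prime` equals the summed
#' path products exactly, and this identity is reported as
#' `identity_gap`. Percent mediated is
#' `100 * (c_total - c_prime) / c_total`, flagged undefined (NA) rather
#' than infinite when the total effect is numerically zero; it can
#' legitimately exceed 100% when the direct effect flips sign (complete
#' mediation).
#'
#' @param data Data.frame with all named columns, complete cases.
#' @param x,y Exposure and outcome column names.
#' @param mediators One (single) or two (parallel/sequential) mediator
#'   column names, ordered: the first mediator is `m1`.
#' @param covariates Covariate column names (default `c("age", "sex")`).
#' @param extra_controls Additional control columns appended to the
#'   covariate set of every equation (e.g. the other VRFs, or BMI).
#' @param topology `"single"`, `"parallel"`, or `"sequential"`; defaults
#'   to `"single"` for one mediator.
#' @return A `mediation_result` with `paths` (and normal-theory SEs and
#'   p-values), `indirect` effects, `percent_mediated`, `identity_gap`,
#'   and `n`.
#' @export
fit_mediation <- function(data, x, y, mediators,
                          covariates = c("age", "sex"),
                          extra_controls = character(0),
                          topology = NULL) {
  mediators <- as.character(mediators)
  topology <- topology %||% if (length(mediators) == 1) "single" else
    "parallel"
  topology <- match.arg(topology, c("single", "parallel", "sequential"))
  if ((topology == "single") != (length(mediators) == 1)) {
    stop("topology '", topology, "' needs ",
         if (topology == "single") "exactly one mediator" else
           "two mediators", call. = FALSE)
  }
  if (length(mediators) > 2) stop("at most two mediators supported",
                                  call. = FALSE)
  covs <- c(covariates, extra_controls)
  overlap <- intersect(mediators, c(x, y, covs))
  if (length(overlap)) {
    stop("mediators must be distinct from x, y and covariates: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  Z <- build_design(data, x, y, mediators, covs)
  n <- nrow(Z)
  G <- crossprod(Z)
  q <- med_quantities(G, x, y, mediators[1],
                      if (length(mediators) > 1) mediators[2] else NULL,
                      covs, topology, n = n, want_se = TRUE)
  pvals <- 2 * stats::pt(-abs(q$paths / q$ses), df = n - length(covs) - 4)
  structure(
    list(x = x, y = y, mediators = mediators, covariates = covs,
         topology = topology, n = n,
         paths = q$paths, path_se = q$ses, path_p = pvals,
         indirect = q$indirect, indirect_total = q$indirect_total,
         percent_mediated = q$percent_mediated,
         identity_gap = q$identity_gap),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("%s mediation: %s -> (%s) -> %s, n = %d\n", x$topology,
              x$x, paste(x$mediators, collapse = ", "), x$y, x$n))
  tab <- data.frame(estimate = round(x$paths, 4))
  if (!all(is.na(x$path_se))) tab$se <- round(x$path_se, 4)
  print(tab)
  cat("indirect:", paste(names(x$indirect), round(x$indirect, 4),
                         sep = " = ", collapse = ", "), "\n")
  pm <- x$percent_mediated
  cat("percent mediated:", if (is.na(pm)) "undefined (total ~ 0)" else
    paste0(round(pm, 1), "%"), "\n")
  if (!is.null(x$boot)) {
    cat("bootstrap CIs (", x$boot$n_boot, " replicates, ",
        100 * x$boot$ci_level, "%):\n", sep = "")
    print(round(x$boot$ci, 4))
  }
  invisible(x)
}

#' Percentile-bootstrap inference for a mediation model
#'
#' Nonparametric subject-level resampling with replacement: each
#' replicate refits every mediation equation (via the cross-product
#' representation, so no data are copied), and percentile confidence
#' intervals at `ci_level` are reported for every path, indirect effect,
#' and the percent mediated. A normal-approximation p-value
#' (estimate over bootstrap SE) is attached to each quantity. Replicates
#' with singular designs are redrawn and counted; more than 1% failures
#' is an error. Results are reproducible under `seed`.
#'
#' @inheritParams fit_mediation
#' @param n_boot Number of bootstrap replicates (at least 200).
#' @param ci_level Confidence level for the percentile intervals.
#' @param seed Integer seed.
#' @return The `mediation_result` from [fit_mediation()] with a `boot`
#'   element: `ci` (matrix of lower/upper bounds), `se`, `p`, `n_boot`,
#'   `failures`.
#' @export
bootstrap_mediation <- function(data, x, y, mediators,
                                covariates = c("age", "sex"),
                                extra_controls = character(0),
                                topology = NULL, n_boot = 1000L,
                                ci_level = 0.95, seed = 1L) {
  if (n_boot < 200) stop("n_boot must be at least 200", call. = FALSE)
  point <- fit_mediation(data, x, y, mediators, covariates,
                         extra_controls, topology)
  covs <- point$covariates
  topology <- point$topology
  Z <- build_design(data, x, y, mediators, covs)
  n <- nrow(Z)
  m1 <- mediators[1]
  m2 <- if (length(mediators) > 1) mediators[2] else NULL
  template <- flatten_quantities(
    med_quantities(crossprod(Z), x, y, m1, m2, covs, topology))
  draws <- matrix(NA_real_, n_boot, length(template),
                  dimnames = list(NULL, names(template)))
  failures <- 0L
  withr::with_seed(seed, {
    b <- 1L
    while (b <= n_boot) {
      w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      Gb <- crossprod(Z * sqrt(w))
      qb <- tryCatch(
        med_quantities(Gb, x, y, m1, m2, covs, topology),
        error = function(e) NULL)
      if (is.null(qb)) {
        failures <- failures + 1L
        if (failures > max(10, 0.01 * n_boot)) {
          stop("more than 1% of bootstrap replicates had singular ",
               "designs", call. = FALSE)
        }
        next
      }
      draws[b, ] <- flatten_quantities(qb)
      b <- b + 1L
    }
  })
  alpha <- (1 - ci_level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  boot_se <- apply(draws, 2, stats::sd, na.rm = TRUE)
  est <- flatten_quantities(
    list(paths = point$paths, indirect = point$indirect,
         indirect_total = point$indirect_total,
         percent_mediated = point$percent_mediated))
  p <- 2 * stats::pnorm(-abs(est / boot_se))
  point$boot <- list(ci = ci, se = boot_se, p = p, n_boot = n_boot,
                     ci_level = ci_level, failures = failures, seed = seed)
  point
}
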