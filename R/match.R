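#' Propensity-score model for a binary exposure
#'
#' Logistic regression of exposure on covariates; sex is handled later by
#' exact matching, not by the model. Perfect or near-perfect separation is
#' rejected with advice to review the covariates or add a caliper.
#'
#' @param data Data.frame with exposure and covariates.
#' @param exposure Name of a binary (0/1 or logical) exposure column.
#' @param covariates Names of covariate columns (e.g. age, head size,
#'   body surface area).
#' @return List with `propensity` (per-subject probabilities) and `model`
#'   (the fitted [stats::glm()]).
#' @export
estimate_propensity <- function(data, exposure, covariates) {
  assert_cols(data, c(exposure, covariates))
  y <- as.integer(data[[exposure]])
  if (!all(y %in% c(0L, 1L))) stop("exposure must be binary", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both exposure classes must be present", call. = FALSE)
  }
  fml <- stats::reformulate(covariates, response = exposure)
  fit <- suppressWarnings(stats::glm(fml, data = data, family = stats::binomial()))
  pr <- stats::fitted(fit)
  if (any(pr > 1 - 1e-8) || any(pr < 1e-8) || !fit$converged) {
    stop("propensity model shows (near-)perfect separation; review ",
         "covariates or use a caliper", call. = FALSE)
  }
  list(propensity = unname(pr), model = fit)
}

smd <- function(x, g) {
  m1 <- mean(x[g]); m0 <- mean(x[!g])
  s <- sqrt((stats::var(x[g]) + stats::var(x[!g])) / 2)
  if (s < .Machine$double.eps^0.5) return(0)
  (m1 - m0) / s
}

#' Greedy 1:1 nearest-neighbour propensity matching, exact on sex
#'
#' Pairs each exposed subject with the unmatched control nearest in
#' propensity score within the same sex stratum. Exposed subjects are
#' processed in descending propensity order (hardest to match first) and
#' controls are consumed without replacement; ties in propensity are
#' broken by subject id, so the pair set is invariant to row order.
#' Exposed subjects with no same-sex control left are reported unmatched,
#' never silently dropped.
#'
#' @param data Data.frame with exposure, sex, and an id column.
#' @param exposure Binary exposure column name.
#' @param propensity Per-subject propensity scores (e.g. from
#'   [estimate_propensity()]).
#' @param sex Column used for exact matching.
#' @param id Subject-id column.
#' @param caliper Optional maximum |propensity difference| for a valid
#'   pair (default none).
#' @param balance_covariates Columns for before/after standardized mean
#'   difference diagnostics.
#' @return A `matched_pairs` object: `pairs` (exposed/control ids and
#'   propensities), `unmatched` ids, and a `balance` table of SMDs.
#' @export
match_nearest <- function(data, exposure, propensity, sex = "sex",
                          id = "subject_id", caliper = NULL,
                          balance_covariates = NULL) {
  assert_cols(data, c(exposure, sex, id))
  if (length(propensity) != nrow(data)) {
    stop("propensity must align with data rows", call. = FALSE)
  }
  exp_flag <- as.logical(data[[exposure]])
  ids <- as.character(data[[id]])
  # canonical order: descending propensity, ties by id
  pairs <- list()
  unmatched <- character(0)
  for (s in unique(data[[sex]])) {
    in_s <- data[[sex]] == s
    ei <- which(in_s & exp_flag)
    ci <- which(in_s & !exp_flag)
    ei <- ei[order(-propensity[ei], ids[ei])]
    ci <- ci[order(propensity[ci], ids[ci])]
    avail <- rep(TRUE, length(ci))
    p_ctrl <- propensity[ci]
    for (e in ei) {
      cand <- which(avail)
      if (!length(cand)) {
        unmatched <- c(unmatched, ids[e])
        next
      }
      d <- abs(p_ctrl[cand] - propensity[e])
      best <- cand[order(d, ids[ci[cand]])[1]]
      if (!is.null(caliper) && abs(p_ctrl[best] - propensity[e]) > caliper) {
        unmatched <- c(unmatched, ids[e])
        next
      }
      avail[best] <- FALSE
      pairs[[length(pairs) + 1L]] <-
        data.frame(exposed_id = ids[e], control_id = ids[ci[best]],
                   propensity_exposed = propensity[e],
                   propensity_control = p_ctrl[best],
                   stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(exposed_id = character(0), control_id = character(0),
               propensity_exposed = numeric(0),
               propensity_control = numeric(0))
  balance <- NULL
  if (!is.null(balance_covariates) && nrow(pairs)) {
    keep <- ids %in% c(pairs$exposed_id, pairs$control_id)
    balance <- do.call(rbind, lapply(balance_covariates, function(cv) {
      data.frame(covariate = cv,
                 smd_before = smd(data[[cv]], exp_flag),
                 smd_after = smd(data[[cv]][keep], exp_flag[keep]),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(pairs = pairs, unmatched = unmatched, balance = balance,
                 mean_distance = if (nrow(pairs))
                   mean(abs(pairs$propensity_exposed -
                              pairs$propensity_control)) else NA_real_),
            class = "matched_pairs")
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat("Matched pairs:", nrow(x$pairs), "(unmatched exposed:",
      length(x$unmatched), ")\n")
  if (!is.null(x$balance)) {
    print(transform(x$balance, smd_before = round(smd_before, 3),
                    smd_after = round(smd_after, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Native-unit outcome contrasts between matched groups
#'
#' For each outcome: group means, mean difference, percent difference
#' relative to the control mean, a t-test between the matched groups
#' (unpaired by default, mirroring repeated two-sample testing of the
#' matched groups; set `paired = TRUE` for the pair-wise variant), and
#' BH-FDR q-values across outcomes.
#'
#' @param data Data.frame holding the outcome columns in native units.
#' @param pairs A `matched_pairs` object.
#' @param outcomes Outcome column names.
#' @param id Subject-id column.
#' @param paired Use a paired t-test.
#' @return Data.frame with one `comparison_record` row per outcome:
#'   `outcome`, `mean_exposed`, `mean_control`, `diff`, `pct_diff`, `t`,
#'   `p`, `q`.
#' @export
paired_compare <- function(data, pairs, outcomes, id = "subject_id",
                           paired = FALSE) {
  stopifnot(inherits(pairs, "matched_pairs"))
  if (!nrow(pairs$pairs)) stop("no matched pairs", call. = FALSE)
  assert_cols(data, c(id, outcomes))
  ids <- as.character(data[[id]])
  ei <- match(pairs$pairs$exposed_id, ids)
  ci <- match(pairs$pairs$control_id, ids)
  res <- lapply(outcomes, function(oc) {
    xe <- data[[oc]][ei]; xc <- data[[oc]][ci]
    ok <- stats::complete.cases(xe, xc)
    xe <- xe[ok]; xc <- xc[ok]
    me <- mean(xe); mc <- mean(xc)
    tt <- if (isTRUE(all.equal(xe, xc))) {
      list(statistic = c(t = 0), p.value = 1)
    } else {
      stats::t.test(xe, xc, paired = paired)
    }
    data.frame(outcome = oc, mean_exposed = me, mean_control = mc,
               diff = me - mc,
               pct_diff = if (abs(mc) > .Machine$double.eps^0.5)
                 100 * (me - mc) / mc else NA_real_,
               t = unname(tt$statistic), p = tt$p.value,
               n_pairs = length(xe), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", class(out))
  out
}
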