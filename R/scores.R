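#' Regress imaging confounders out of latent scores
#'
#' Replaces each latent score by its residual from an OLS regression on
#' the confounders (intercept included) and re-standardizes it.
#' Deconfounding is a projection, so applying it twice equals applying it
#' once. Collinear confounder columns are dropped with a warning.
#'
#' @param scores A `score_set` or data.frame of latent scores (a
#'   `subject_id` column, if present, is passed through).
#' @param confounders Data.frame of complete confounder columns, aligned
#'   with `scores` rows.
#' @return The score set with residualized, re-standardized scores; the
#'   `deconfounded` attribute records the latents treated and the
#'   confounders retained.
#' @export
deconfound <- function(scores, confounders) {
  df <- as.data.frame(scores)
  confounders <- as.data.frame(confounders)
  if (nrow(df) != nrow(confounders)) {
    stop("scores and confounders must have the same rows", call. = FALSE)
  }
  if (anyNA(confounders)) {
    stop("confounder columns must be complete", call. = FALSE)
  }
  C <- cbind(`(Intercept)` = 1, as.matrix(confounders))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    dropped <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    warning("dropping collinear confounder(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    C <- C[, qrC$pivot[seq_len(qrC$rank)], drop = FALSE]
    qrC <- qr(C)
  }
  latents <- setdiff(names(df), "subject_id")
  for (cl in latents) {
    df[[cl]] <- std1(qr.resid(qrC, df[[cl]]), cl)
  }
  attr(df, "deconfounded") <- list(
    latents = latents,
    confounders = setdiff(colnames(C), "(Intercept)"))
  class(df) <- unique(c("score_set", class(df)))
  df
}

#' Derive all latent scores from a prepared cohort
#'
#' Runs the full latent-variable stage on a prepared (transformed,
#' complete-case) cohort:
#'
#' * `gVRF` — single-factor CFA over the z-scored 8 VRF indicators;
#' * `g` — single-factor CFA over the z-scored 4 (transformed) cognitive
#'   tests;
#' * `heart_pc*` — PCA of the z-scored heart features with CV-chosen
#'   component count;
#' * passthrough brain measures `atrophy` (total brain volume), `gmv`
#'   (grey matter volume) and `wmh` (white-matter hyperintensity volume),
#'   standardized;
#' * `gFA` / `gMD` — single-factor CFAs over the tract-wise FA and MD
#'   columns;
#' * `brain_pc*` — PCA over all z-scored brain IDPs, CV-chosen count;
#' * `heart_cc*` / `brain_cc*` — both sides of the retained heart-brain
#'   canonical modes;
#' * `vrf_agg` — the aggregate VRF count, passed through if present.
#'
#' All scores are standardized. Deconfounding is a separate step
#' ([deconfound()]) so both raw and deconfounded variants can be
#' reported.
#'
#' @param cohort A prepared [cohort_table].
#' @param max_pcs Maximum candidate components per PCA block.
#' @param max_modes Maximum canonical modes to extract.
#' @param min_pcs Floor on the number of PCA components carried into the
#'   score set (the CV choice is recorded in the model either way); the
#'   default 0 keeps exactly the CV choice.
#' @param atrophy_col,gmv_col,wmh_col Columns passed through as individual
#'   brain measures (set to `NULL` to skip).
#' @param seed Seed for the CV fold assignments.
#' @return A list with `scores` (a `score_set` data.frame, one column per
#'   latent plus `subject_id`) and `models` (the fitted `latent_model`s).
#' @export
derive_latents <- function(cohort, max_pcs = 10L, max_modes = 10L,
                           min_pcs = 0L,
                           atrophy_col = "brn_tbv", gmv_col = "brn_gmv",
                           wmh_col = "brn_wmh", seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  data <- cohort_data(cohort)
  if (anyNA(data)) {
    stop("cohort contains missing values; run complete_case_filter first",
         call. = FALSE)
  }
  vrf_cols <- role_columns(cohort, c("vrf_binary", "vrf_continuous"))
  cog_cols <- role_columns(cohort, "cognitive")
  heart_cols <- role_columns(cohort, "heart_feature")
  brain_cols <- role_columns(cohort, c("brain_volume", "brain_fa",
                                       "brain_md", "brain_wmh"))
  fa_cols <- role_columns(cohort, "brain_fa")
  md_cols <- role_columns(cohort, "brain_md")

  models <- list()
  scores <- data.frame(subject_id = data$subject_id,
                       stringsAsFactors = FALSE)

  zblock <- function(cols) {
    as.matrix(zscore_columns(data, cols)$cohort[, cols, drop = FALSE])
  }

  if (length(vrf_cols) >= 3) {
    Xv <- zblock(vrf_cols)
    models$gvrf <- fit_cfa(Xv)
    scores$gVRF <- cfa_scores(models$gvrf, Xv)
  }
  if (length(cog_cols) >= 3) {
    Xc <- zblock(cog_cols)
    models$g <- fit_cfa(Xc)
    scores$g <- cfa_scores(models$g, Xc)
  }
  if ("vrf_count" %in% names(data)) {
    scores$vrf_agg <- std1(data$vrf_count, "vrf_count")
  }

  Xh <- NULL
  if (length(heart_cols) >= 2) {
    Xh <- as.matrix(data[, heart_cols, drop = FALSE])
    models$heart_pca <- fit_pca(Xh, max_k = min(max_pcs,
                                                length(heart_cols) - 1L),
                                seed = child_seed(seed, 1))
    k <- max(models$heart_pca$n_components, min_pcs)
    if (k > 0) {
      S <- pca_scores(models$heart_pca, Xh, k = k)
      colnames(S) <- paste0("heart_pc", seq_len(k))
      scores <- cbind(scores, S)
    }
  }

  for (pp in list(c(atrophy_col, "atrophy"), c(gmv_col, "gmv"),
                  c(wmh_col, "wmh"))) {
    if (!is.null(pp[1]) && pp[1] %in% names(data)) {
      scores[[pp[2]]] <- std1(data[[pp[1]]], pp[1])
    }
  }

  if (length(fa_cols) >= 3) {
    Xf <- zblock(fa_cols)
    models$gfa <- fit_cfa(Xf)
    scores$gFA <- cfa_scores(models$gfa, Xf)
  }
  if (length(md_cols) >= 3) {
    Xm <- zblock(md_cols)
    models$gmd <- fit_cfa(Xm)
    scores$gMD <- cfa_scores(models$gmd, Xm)
  }

  Xb <- NULL
  if (length(brain_cols) >= 2) {
    Xb <- as.matrix(data[, brain_cols, drop = FALSE])
    models$brain_pca <- fit_pca(Xb, max_k = min(max_pcs,
                                                length(brain_cols) - 1L),
                                seed = child_seed(seed, 2))
    k <- max(models$brain_pca$n_components, min_pcs)
    if (k > 0) {
      S <- pca_scores(models$brain_pca, Xb, k = k)
      colnames(S) <- paste0("brain_pc", seq_len(k))
      scores <- cbind(scores, S)
    }
  }

  if (!is.null(Xh) && !is.null(Xb)) {
    models$cca <- fit_cca(Xh, Xb,
                          max_modes = min(max_modes, ncol(Xh), ncol(Xb)),
                          seed = child_seed(seed, 3))
    m <- models$cca$n_components
    if (m > 0) {
      cs <- cca_scores(models$cca, Xh, Xb, k = m)
      colnames(cs$x) <- paste0("heart_cc", seq_len(m))
      colnames(cs$y) <- paste0("brain_cc", seq_len(m))
      scores <- cbind(scores, cs$x, cs$y)
    }
  }

  class(scores) <- unique(c("score_set", class(scores)))
  attr(scores, "deconfounded") <- NULL
  list(scores = scores, models = models)
}

#' Names of the latent-score columns in a score set
#'
#' @param scores A `score_set` data.frame.
#' @return Character vector of latent names (everything but
#'   `subject_id`).
#' @export
latent_names <- function(scores) {
  setdiff(names(as.data.frame(scores)), "subject_id")
}
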