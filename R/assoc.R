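#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), computed
#' with [stats::p.adjust()]. Input values outside `[0, 1]` are rejected.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values outside [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Additional variance explained by a predictor beyond covariates
#'
#' The R-squared of the model `y ~ covariates + x` minus that of
#' `y ~ covariates` alone, clipped at 0 against negative round-off. With
#' standardized `y` and `x` and no covariates this is the squared
#' standardized slope.
#'
#' @param y,x Numeric vectors (complete cases, aligned).
#' @param covariates Optional data.frame/matrix of covariates.
#' @return Proportion of variance in `[0, 1]`.
#' @export
additional_r2 <- function(y, x, covariates = NULL) {
  if (stats::sd(y) < .Machine$double.eps^0.5) {
    stop("zero-variance outcome", call. = FALSE)
  }
  if (is.null(covariates) || NCOL(covariates) == 0) {
    r2_cov <- 0
    full <- stats::lm(y ~ x)
  } else {
    C <- as.data.frame(covariates)
    r2_cov <- summary(stats::lm(y ~ ., data = C))$r.squared
    full <- stats::lm(y ~ ., data = cbind(C, x = x))
  }
  max(0, summary(full)$r.squared - r2_cov)
}

#' Pairwise latent association models with age and sex adjustment
#'
#' Linearly models every ordered pair of latents: the dependent latent as
#' a function of the independent latent, age, and sex. With L latents this
#' yields L(L-1) records. Reports the standardized coefficient on the
#' independent latent, its SE and p-value, the additional R-squared the
#' latent contributes beyond the covariates, and BH-FDR q-values over the
#' whole family of models.
#'
#' @param scores A `score_set` or data.frame of standardized latent
#'   scores.
#' @param covariates Data.frame with the adjustment covariates (age,
#'   sex), aligned with `scores`; age is centered internally, binary sex
#'   is left unscaled.
#' @param latents Latents to include (default: all score columns).
#' @return Data.frame of `association_record` rows: `dependent`,
#'   `independent`, `beta`, `se`, `p`, `q`, `additional_r2`.
#' @export
pairwise_latent_models <- function(scores, covariates,
                                   latents = latent_names(scores)) {
  df <- as.data.frame(scores)
  if (length(latents) < 2) {
    stop("need at least 2 latents for pairwise models", call. = FALSE)
  }
  C <- as.data.frame(covariates)
  num <- vapply(C, function(v) length(unique(v)) > 2, TRUE)
  C[num] <- lapply(C[num], function(v) v - mean(v))
  pairs <- expand.grid(dependent = latents, independent = latents,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$dependent != pairs$independent, ]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    yv <- df[[pairs$dependent[i]]]
    xv <- df[[pairs$independent[i]]]
    fit <- stats::lm(yv ~ xv + ., data = C)
    sm <- summary(fit)$coefficients["xv", ]
    data.frame(dependent = pairs$dependent[i],
               independent = pairs$independent[i],
               beta = unname(sm["Estimate"]), se = unname(sm["Std. Error"]),
               p = unname(sm["Pr(>|t|)"]),
               additional_r2 = additional_r2(yv, xv, C),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out <- out[, c("dependent", "independent", "beta", "se", "p", "q",
                 "additional_r2")]
  class(out) <- c("association_table", class(out))
  rownames(out) <- NULL
  out
}
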