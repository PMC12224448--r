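# Core CCA on covariance matrices via Cholesky whitening + SVD.
# Returns weights (columns per mode) normalized so the training-score
# variance is 1, and the canonical correlations (singular values).
cca_core <- function(Sxx, Syy, Sxy, n_modes, ridge = 0) {
  if (ridge > 0) {
    Sxx <- Sxx + diag(ridge * mean(diag(Sxx)), nrow(Sxx))
    Syy <- Syy + diag(ridge * mean(diag(Syy)), nrow(Syy))
  }
  Rx <- chol(Sxx)
  Ry <- chol(Syy)
  # K = Sxx^{-1/2} Sxy Syy^{-1/2} with the Cholesky square roots
  K <- t(backsolve(Rx, Sxy, transpose = TRUE))
  K <- t(backsolve(Ry, K, transpose = TRUE))
  sv <- svd(K, nu = n_modes, nv = n_modes)
  Wx <- backsolve(Rx, sv$u[, seq_len(n_modes), drop = FALSE])
  Wy <- backsolve(Ry, sv$v[, seq_len(n_modes), drop = FALSE])
  list(wx = Wx, wy = Wy, cor = sv$d[seq_len(n_modes)])
}

safe_cov <- function(Z) crossprod(Z) / (nrow(Z) - 1)

#' Canonical correlation analysis with permutation-calibrated mode count
#'
#' Extracts paired heart/brain weight vectors whose projected scores are
#' maximally correlated (modes ranked by canonical correlation), from the
#' z-scored feature blocks. The number of modes to keep is chosen by
#' subject-level cross-validation: for each mode, the mean held-out
#' correlation across folds is compared with the 95th percentile of its
#' permutation null (held-out scores of one block shuffled across
#' subjects); modes are retained until the first failure. A small ridge
#' (`1e-3 * mean diagonal`) is added to a within-block covariance only
#' when it is numerically singular, with a warning.
#'
#' @param X,Y Heart-side and brain-side feature blocks (subjects in
#'   rows).
#' @param max_modes Number of modes to extract (at most the smaller block
#'   width).
#' @param cv_folds Folds for the held-out correlation.
#' @param n_perm Permutations per mode for the retention null.
#' @param perm_q Null quantile a mode must exceed (default 0.95).
#' @param seed Seed controlling folds and permutations.
#' @return A `latent_model` of kind `"cca"`: `weights_x`, `weights_y`,
#'   training `canonical_correlations`, retained `n_components`, the CV
#'   summary in `fit_meta$cv`, and the per-block scaling statistics.
#' @export
fit_cca <- function(X, Y, max_modes = NULL, cv_folds = 5L, n_perm = 100L,
                    perm_q = 0.95, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("blocks must have the same subjects",
                               call. = FALSE)
  n <- nrow(X)
  max_modes <- max_modes %||% min(10L, ncol(X), ncol(Y))
  if (max_modes > min(ncol(X), ncol(Y))) {
    stop("max_modes exceeds the smaller block width", call. = FALSE)
  }
  if (n <= max(ncol(X), ncol(Y)) + cv_folds) {
    stop("too few subjects for CCA on blocks this wide", call. = FALSE)
  }
  xn <- colnames(X) %||% paste0("hx", seq_len(ncol(X)))
  yn <- colnames(Y) %||% paste0("by", seq_len(ncol(Y)))

  zs <- function(M) {
    ctr <- colMeans(M); scl <- apply(M, 2, stats::sd)
    if (any(scl < .Machine$double.eps^0.5)) {
      stop("zero-variance column in CCA block", call. = FALSE)
    }
    list(Z = sweep(sweep(M, 2, ctr), 2, scl, `/`), center = ctr,
         scale = scl)
  }
  zx <- zs(X); zy <- zs(Y)

  fit_on <- function(Zx, Zy) {
    Sxx <- safe_cov(Zx); Syy <- safe_cov(Zy)
    Sxy <- crossprod(Zx, Zy) / (nrow(Zx) - 1)
    ridge <- 0
    ok <- tryCatch({chol(Sxx); chol(Syy); TRUE},
                   error = function(e) FALSE)
    if (!ok || rcond(Sxx) < 1e-10 || rcond(Syy) < 1e-10) {
      ridge <- 1e-3
      warning("singular within-block covariance: ridge ",
              "1e-3 * mean(diag) applied", call. = FALSE)
    }
    cca_core(Sxx, Syy, Sxy, max_modes, ridge)
  }

  # cross-validated held-out correlations and their permutation nulls
  withr::with_seed(seed, {
    fold_id <- sample(rep_len(seq_len(cv_folds), n))
    heldout <- matrix(NA_real_, cv_folds, max_modes)
    null_ho <- array(NA_real_, c(cv_folds, max_modes, n_perm))
    for (f in seq_len(cv_folds)) {
      tr <- fold_id != f
      fit_f <- fit_on(zx$Z[tr, , drop = FALSE], zy$Z[tr, , drop = FALSE])
      sx <- zx$Z[!tr, , drop = FALSE] %*% fit_f$wx
      sy <- zy$Z[!tr, , drop = FALSE] %*% fit_f$wy
      m <- nrow(sx)
      for (j in seq_len(max_modes)) {
        heldout[f, j] <- stats::cor(sx[, j], sy[, j])
      }
      for (b in seq_len(n_perm)) {
        pi_b <- sample.int(m)
        for (j in seq_len(max_modes)) {
          null_ho[f, j, b] <- stats::cor(sx[, j], sy[pi_b, j])
        }
      }
    }
  })
  mean_ho <- colMeans(heldout)
  null_mean <- apply(null_ho, c(2, 3), mean)  # modes x perms
  crit <- apply(null_mean, 1, stats::quantile, probs = perm_q)
  retained <- 0L
  for (j in seq_len(max_modes)) {
    if (is.finite(mean_ho[j]) && mean_ho[j] > crit[j]) {
      retained <- j
    } else break
  }

  fit <- fit_on(zx$Z, zy$Z)
  # orient each mode so the largest-|weight| heart feature is positive;
  # flip both sides together to preserve the (non-negative) correlation
  flips <- rep(FALSE, max_modes)
  for (j in seq_len(max_modes)) {
    if (fit$wx[which.max(abs(fit$wx[, j])), j] < 0) {
      fit$wx[, j] <- -fit$wx[, j]
      fit$wy[, j] <- -fit$wy[, j]
      flips[j] <- TRUE
    }
  }
  rownames(fit$wx) <- xn; rownames(fit$wy) <- yn
  colnames(fit$wx) <- colnames(fit$wy) <- paste0("cc", seq_len(max_modes))
  structure(
    list(kind = "cca", indicator_names = list(x = xn, y = yn),
         weights_x = fit$wx, weights_y = fit$wy,
         canonical_correlations = fit$cor,
         n_components = retained,
         sign_flipped = flips,
         center_x = zx$center, scale_x = zx$scale,
         center_y = zy$center, scale_y = zy$scale,
         fit_meta = list(cv = data.frame(mode = seq_len(max_modes),
                                         heldout_cor = mean_ho,
                                         null_q = unname(crit)),
                         n = n)),
    class = "latent_model")
}

#' Per-subject scores on retained canonical modes
#'
#' @param model A `latent_model` from [fit_cca()].
#' @param X,Y Feature blocks with the fitted columns.
#' @param k Number of modes (default: retained count).
#' @param standardize Standardize each score column (default `TRUE`).
#' @return List with matrices `x` and `y` of mode scores (n x k).
#' @export
cca_scores <- function(model, X, Y, k = model$n_components,
                       standardize = TRUE) {
  stopifnot(inherits(model, "latent_model"), model$kind == "cca")
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.null(colnames(X))) X <- X[, model$indicator_names$x, drop = FALSE]
  if (!is.null(colnames(Y))) Y <- Y[, model$indicator_names$y, drop = FALSE]
  if (k == 0) {
    return(list(x = matrix(numeric(0), nrow(X), 0),
                y = matrix(numeric(0), nrow(Y), 0)))
  }
  Zx <- sweep(sweep(X, 2, model$center_x), 2, model$scale_x, `/`)
  Zy <- sweep(sweep(Y, 2, model$center_y), 2, model$scale_y, `/`)
  sx <- Zx %*% model$weights_x[, seq_len(k), drop = FALSE]
  sy <- Zy %*% model$weights_y[, seq_len(k), drop = FALSE]
  if (standardize) {
    sx <- apply(sx, 2, std1); sy <- apply(sy, 2, std1)
  }
  colnames(sx) <- colnames(sy) <- paste0("cc", seq_len(k))
  list(x = sx, y = sy)
}
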