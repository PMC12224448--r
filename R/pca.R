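# Rank-k EM-PCA reconstruction of a matrix with missing cells: iterate
# column-mean centering, truncated SVD of the completed matrix, and
# replacement of the missing cells by the rank-k reconstruction. k = 0 is
# the column-mean model.
empca_impute <- function(X, mask, k, max_iter = 100L, tol = 1e-5) {
  Xc <- X
  mu <- colMeans(X, na.rm = FALSE)
  obs_mu <- vapply(seq_len(ncol(X)), function(j) {
    mean(X[!mask[, j], j])
  }, 0)
  for (j in seq_len(ncol(X))) Xc[mask[, j], j] <- obs_mu[j]
  prev <- Xc[mask]
  for (it in seq_len(max_iter)) {
    mu <- colMeans(Xc)
    Xd <- sweep(Xc, 2, mu)
    recon <- if (k > 0) {
      sv <- svd(Xd, nu = k, nv = k)
      sweep(sv$u %*% (diag(sv$d[seq_len(k)], k) %*% t(sv$v)), 2, mu, `+`)
    } else {
      matrix(mu, nrow(X), ncol(X), byrow = TRUE)
    }
    Xc[mask] <- recon[mask]
    cur <- Xc[mask]
    if (length(cur) == 0) break
    delta <- sqrt(mean((cur - prev)^2))
    if (delta < tol) break
    prev <- cur
  }
  recon
}

# Element-wise (Wold) cross-validation curve: delete random cells fold by
# fold, impute them by rank-k EM-PCA, score held-out MSE.
pca_cv_curve <- function(X, ks, folds = 5L, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  withr::with_seed(seed, {
    fold_id <- matrix(sample(rep_len(seq_len(folds), n * p)), n, p)
  })
  mse <- matrix(NA_real_, length(ks), folds,
                dimnames = list(paste0("k", ks), NULL))
  for (f in seq_len(folds)) {
    mask <- fold_id == f
    # guard: never blank out an entire column or row
    mask[, colSums(!mask) < 2] <- FALSE
    for (i in seq_along(ks)) {
      recon <- empca_impute(X, mask, ks[i])
      mse[i, f] <- mean((X[mask] - recon[mask])^2)
    }
  }
  data.frame(k = ks, mse = rowMeans(mse),
             se = apply(mse, 1, stats::sd) / sqrt(folds))
}

#' Principal component analysis with cross-validated component count
#'
#' Computes unrotated principal components of the z-scored feature block
#' and chooses how many to keep by element-wise (Wold) cross-validation:
#' random cells are deleted, imputed by rank-k EM-PCA, and scored by
#' held-out reconstruction error; among candidate ranks, the smallest k
#' whose mean CV error is within one standard error of the minimum is
#' retained (the one-SE rule), which guards against the naive-CV tendency
#' to keep the maximum rank. k = 0 (the column-mean model) is a candidate,
#' so blocks of pure noise retain no components. Each retained component
#' is oriented so its largest-magnitude weight is positive.
#'
#' @param X Numeric matrix or data.frame (features in columns).
#' @param max_k Maximum candidate rank (`< min(n, p)`).
#' @param cv_folds Number of element-deletion folds.
#' @param one_se Use the one-SE rule (default) rather than the bare
#'   minimum.
#' @param seed Seed for the fold assignment.
#' @return A `latent_model` of kind `"pca"`: `weights` (p x max_k rotation
#'   matrix), `variance_explained`, selected `n_components`, the CV curve
#'   in `fit_meta$cv`, and the centering/scaling statistics.
#' @export
fit_pca <- function(X, max_k = NULL, cv_folds = 5L, one_se = TRUE,
                    seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  max_k <- max_k %||% min(n - 1L, p - 1L, 10L)
  if (max_k >= min(n, p)) {
    stop("max_k must be smaller than min(n, p)", call. = FALSE)
  }
  feature_names <- colnames(X) %||% paste0("x", seq_len(p))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl < .Machine$double.eps^0.5)) {
    stop("zero-variance column(s): ",
         paste(feature_names[scl < .Machine$double.eps^0.5], collapse = ", "),
         call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  cv <- pca_cv_curve(Z, ks = 0:max_k, folds = cv_folds, seed = seed)
  i_min <- which.min(cv$mse)
  k <- if (one_se) {
    thresh <- cv$mse[i_min] + cv$se[i_min]
    cv$k[which(cv$mse <= thresh)[1]]
  } else cv$k[i_min]

  sv <- svd(Z)
  rank_eff <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank_eff) {
    warning("rank-deficient block: truncating k from ", k, " to ", rank_eff,
            call. = FALSE)
    k <- rank_eff
  }
  W <- sv$v[, seq_len(max(max_k, 1)), drop = FALSE]
  flips <- rep(FALSE, ncol(W))
  for (j in seq_len(ncol(W))) {
    if (W[which.max(abs(W[, j])), j] < 0) {
      W[, j] <- -W[, j]
      flips[j] <- TRUE
    }
  }
  rownames(W) <- feature_names
  colnames(W) <- paste0("pc", seq_len(ncol(W)))
  structure(
    list(kind = "pca", indicator_names = feature_names,
         weights = W,
         variance_explained = sv$d^2 / sum(sv$d^2),
         n_components = as.integer(k),
         sign_flipped = flips,
         center = ctr, scale = scl,
         fit_meta = list(cv = cv, n = n)),
    class = "latent_model")
}

#' Component scores for a fitted PCA model
#'
#' Projects (new) data onto the retained components using the training
#' centering and scaling statistics.
#'
#' @param model A `latent_model` from [fit_pca()].
#' @param X Feature matrix with the fitted columns.
#' @param k Number of components to return (default: the CV-selected
#'   count).
#' @param standardize Standardize each score column (default `TRUE`).
#' @return Matrix of per-subject component scores (n x k).
#' @export
pca_scores <- function(model, X, k = model$n_components,
                       standardize = TRUE) {
  stopifnot(inherits(model, "latent_model"), model$kind == "pca")
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    X <- X[, model$indicator_names, drop = FALSE]
  }
  if (k == 0) {
    return(matrix(numeric(0), nrow(X), 0))
  }
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  S <- Z %*% model$weights[, seq_len(k), drop = FALSE]
  if (standardize) S <- apply(S, 2, std1)
  colnames(S) <- paste0("pc", seq_len(k))
  S
}
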