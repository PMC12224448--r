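#' Single-factor confirmatory factor analysis by maximum likelihood
#'
#' Fits the one-factor model `Sigma = lambda lambda' + Psi` to the sample
#' correlation matrix of standardized indicators, with the factor variance
#' fixed at 1 so the loadings are standardized and directly comparable
#' across indicators. Estimation minimizes the ML discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` with analytic gradients
#' (L-BFGS-B). Uniquenesses are bounded below at `psi_floor`; a solution
#' pinned at the floor (a Heywood case) is clamped with a warning. Binary
#' indicators are treated as continuous. The fitted factor is oriented so
#' that the indicator with the largest absolute loading has a positive
#' loading.
#'
#' @param X Numeric matrix or data.frame of indicators (at least 3
#'   columns); standardized internally.
#' @param psi_floor Lower bound for the uniquenesses.
#' @param max_iter Maximum optimizer iterations.
#' @return A `latent_model` of kind `"cfa"` with elements `loadings`,
#'   `uniquenesses`, `determinacy`, `sign_flipped`, and `fit_meta`
#'   (log-likelihood, discrepancy, gradient norm, convergence flag).
#' @examples
#' lam <- c(0.8, 0.7, 0.6, 0.5)
#' f <- rnorm(500)
#' X <- sapply(lam, function(l) l * f + sqrt(1 - l^2) * rnorm(500))
#' fit <- fit_cfa(X)
#' fit$loadings
#' @export
fit_cfa <- function(X, psi_floor = 0.005, max_iter = 500L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 3) stop("single-factor CFA needs at least 3 indicators",
                  call. = FALSE)
  n <- nrow(X)
  if (n <= 2 * p + 1) stop("too few rows for ", p, " indicators",
                           call. = FALSE)
  ind_names <- colnames(X) %||% paste0("x", seq_len(p))
  S <- stats::cor(X)
  if (anyNA(S)) stop("indicators contain missing or constant columns",
                     call. = FALSE)

  e1 <- eigen(S, symmetric = TRUE)
  lam0 <- e1$vectors[, 1] * sqrt(max(e1$values[1], 1))
  lam0 <- pmin(pmax(lam0, -0.95), 0.95)
  psi0 <- pmax(1 - lam0^2, 0.1)

  unpack <- function(par) list(lam = par[1:p], psi = par[(p + 1):(2 * p)])
  discrepancy <- function(par) {
    th <- unpack(par)
    Sigma <- tcrossprod(th$lam) + diag(th$psi, p)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Sinv <- chol2inv(ch)
    2 * sum(log(diag(ch))) + sum(Sinv * S) -
      determinant(S, logarithm = TRUE)$modulus[1] - p
  }
  gradient <- function(par) {
    th <- unpack(par)
    Sigma <- tcrossprod(th$lam) + diag(th$psi, p)
    Sinv <- chol2inv(chol(Sigma))
    B <- Sinv %*% (Sigma - S) %*% Sinv
    c(2 * as.vector(B %*% th$lam), diag(B))
  }
  opt <- stats::optim(c(lam0, psi0), discrepancy, gradient,
                      method = "L-BFGS-B",
                      lower = c(rep(-0.999, p), rep(psi_floor, p)),
                      upper = c(rep(0.999, p), rep(10, p)),
                      control = list(maxit = max_iter))
  th <- unpack(opt$par)
  gnorm <- sqrt(sum(gradient(opt$par)^2))
  if (opt$convergence != 0 && gnorm > 1e-3) {
    stop("CFA did not converge after ", max_iter,
         " iterations (gradient norm ", signif(gnorm, 3), ")",
         call. = FALSE)
  }
  heywood <- th$psi <= psi_floor + 1e-8
  if (any(heywood)) {
    warning("Heywood case: uniqueness clamped at ", psi_floor, " for ",
            paste(ind_names[heywood], collapse = ", "), call. = FALSE)
    th$psi[heywood] <- psi_floor
  }
  flipped <- FALSE
  if (th$lam[which.max(abs(th$lam))] < 0) {
    th$lam <- -th$lam
    flipped <- TRUE
  }
  Sigma <- tcrossprod(th$lam) + diag(th$psi, p)
  Sinv <- chol2inv(chol(Sigma))
  loglik <- -n / 2 * (p * log(2 * pi) +
                        determinant(Sigma, logarithm = TRUE)$modulus[1] +
                        sum(Sinv * S))
  structure(
    list(kind = "cfa", indicator_names = ind_names,
         loadings = stats::setNames(th$lam, ind_names),
         uniquenesses = stats::setNames(th$psi, ind_names),
         n_components = 1L,
         determinacy = sqrt(drop(crossprod(th$lam, Sinv %*% th$lam))),
         score_weights = drop(Sinv %*% th$lam),
         sign_flipped = flipped,
         fit_meta = list(loglik = as.numeric(loglik),
                         discrepancy = opt$value,
                         grad_norm = gnorm, n = n,
                         converged = opt$convergence == 0,
                         heywood = any(heywood))),
    class = "latent_model")
}

#' Factor scores for a fitted single-factor model
#'
#' Regression-method (Thomson) scores `lambda' Sigma^-1 x` on the
#' standardized indicators, re-standardized to mean 0 and SD 1. The
#' correlation between these scores and the true factor is bounded by the
#' model's factor-score determinacy `sqrt(lambda' Sigma^-1 lambda)`.
#'
#' @param model A `latent_model` from [fit_cfa()].
#' @param X Indicator matrix with the same columns the model was fitted
#'   on.
#' @return Numeric vector of standardized factor scores.
#' @export
cfa_scores <- function(model, X) {
  stopifnot(inherits(model, "latent_model"), model$kind == "cfa")
  X <- as.matrix(X)
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), model$indicator_names)) {
    if (!all(model$indicator_names %in% colnames(X))) {
      stop("indicator columns do not match the fitted model", call. = FALSE)
    }
    X <- X[, model$indicator_names, drop = FALSE]
  }
  if (ncol(X) != length(model$loadings)) {
    stop("indicator columns do not match the fitted model", call. = FALSE)
  }
  raw <- scale(X) %*% model$score_weights
  if (stats::sd(raw) < .Machine$double.eps^0.5) {
    stop("degenerate factor scores (all loadings ~0?)", call. = FALSE)
  }
  drop(std1(raw, "factor scores"))
}

#' @export
print.latent_model <- function(x, ...) {
  cat("Latent model (", x$kind, "), ", x$n_components, " component(s)\n",
      sep = "")
  if (x$kind == "cfa") {
    print(round(rbind(loading = x$loadings, uniqueness = x$uniquenesses), 3))
    cat("determinacy:", round(x$determinacy, 3), "\n")
  } else if (x$kind == "pca") {
    cat("variance explained:",
        paste(round(x$variance_explained[seq_len(min(5, length(x$variance_explained)))], 3),
              collapse = ", "), "...\n")
  } else if (x$kind == "cca") {
    cat("canonical correlations:",
        paste(round(x$canonical_correlations, 3), collapse = ", "), "\n")
    cat("retained modes:", x$n_components, "\n")
  }
  invisible(x)
}
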