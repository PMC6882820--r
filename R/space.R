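#' Joint sparse regression (SPACE) for a fixed penalty
#'
#' Estimates the partial correlation matrix by minimizing the joint sparse
#' regression objective
#' \deqn{\frac12 \sum_{i=1}^p \Big\| X_i - \sum_{j\ne i} \rho_{ij} \sqrt{\tfrac{\omega_{jj}}{\omega_{ii}}} X_j \Big\|^2 + \lambda_3 \sum_{i<j} |\rho_{ij}|,}
#' where each \eqn{\rho_{ij}} is a single parameter shared by the regressions
#' of node i on j and of node j on i, and \eqn{\omega_{ii}} is the residual
#' precision of node i.  The solver alternates active coordinate descent on
#' \eqn{\rho} (each update a soft threshold of a residual inner product
#' aggregated over both regressions) with \eqn{\omega_{ii}} re-estimated as
#' inverse mean residual variances; it starts from \eqn{\rho = 0},
#' \eqn{\omega_{ii} = 1/\mathrm{var}(X_i)} and stops when the relative
#' objective change falls below `tol`.
#'
#' @param X Centered data matrix.
#' @param lambda3 Positive penalty on the partial correlations.
#' @param max_outer Maximum number of outer (rho / omega) alternations.
#' @param tol Relative objective-change tolerance.
#' @param warm Optional previous `space_fit` for warm starting a path.
#' @return Object of class `space_fit`: `gamma` (partial correlation matrix,
#'   unit diagonal), `omega_diag` (residual precisions \eqn{\omega_{ii}}),
#'   `rss` (per-node residual sums of squares), `lambda3`, `objective`,
#'   `converged`, `iterations`.
#' @export
fit_space <- function(X, lambda3, max_outer = 50, tol = 1e-6, warm = NULL) {
  if (lambda3 < 0) stop("lambda3 must be positive", call. = FALSE)
  res <- space_cd(X, lambda3, tol, max_outer,
                  if (is.null(warm)) NULL else warm$rho,
                  if (is.null(warm)) NULL else warm$omega_diag)
  if (!res$converged) {
    warning(sprintf("SPACE stopped after %d outer iterations (objective %.6g)",
                    res$iterations, res$objective))
  }
  gamma <- res$rho
  diag(gamma) <- 1
  structure(list(gamma = gamma, rho = res$rho, omega_diag = drop(res$w),
                 rss = drop(res$rss), lambda3 = lambda3,
                 objective = res$objective,
                 converged = res$converged, iterations = res$iterations),
            class = "space_fit")
}

#' Penalty grid for SPACE
#'
#' 100 equidistant values from
#' \eqn{\sqrt n\,\Phi^{-1}(1 - 0.9/(2p^2))} to
#' \eqn{\sqrt n\,\Phi^{-1}(1 - 10^{-4}/(2p^2))}: the endpoints are the
#' finite-sample penalty levels at false-positive bounds 0.9 and 1e-4.
#'
#' @param n Sample count.
#' @param p Variable count.
#' @return Increasing numeric vector of length 100.
#' @export
space_grid <- function(n, p) {
  if (n < 2 || p < 2) stop("need n >= 2 and p >= 2", call. = FALSE)
  lower <- sqrt(n) * stats::qnorm(1 - 0.9 / (2 * p^2))
  upper <- sqrt(n) * stats::qnorm(1 - 1e-4 / (2 * p^2))
  seq(lower, upper, length.out = 100)
}

# SPACE path over a grid (descending, warm starts); list of space_fit in
# grid order
space_path <- function(X, grid, max_outer = 50, tol = 1e-6) {
  ord <- order(grid, decreasing = TRUE)
  fits <- vector("list", length(grid))
  warm <- NULL
  for (k in ord) {
    fit <- suppressWarnings(fit_space(X, grid[k], max_outer = max_outer, tol = tol,
                                      warm = warm))
    fits[[k]] <- fit
    warm <- fit
  }
  fits
}

# held-out prediction error of a SPACE fit: predictor weights
# rho_ij * sqrt(omega_jj / omega_ii)
space_pred_error <- function(fit, Xtest) {
  w <- fit$omega_diag
  B <- fit$rho * sqrt(outer(1 / w, w))  # B[i, j] = rho_ij sqrt(w_j / w_i)
  diag(B) <- 0
  resid <- Xtest - Xtest %*% t(B)
  sum(resid^2)
}

#' Cross-validation curve for SPACE
#'
#' K-fold loss
#' \deqn{\mathrm{CV}(\lambda_3) = \sum_k \sum_i \Big\| X_i^k - \sum_{j\ne i} \hat\rho_{ij}\sqrt{\tfrac{\hat\omega_{jj}}{\hat\omega_{ii}}} X_j^k \Big\|^2,}
#' with the fit recomputed on the retained folds at every grid value.
#'
#' @param X Centered data matrix.
#' @param grid Penalty grid (see [space_grid()]).
#' @param folds Fold assignment from [make_folds()].
#' @return A `cv_curve` object.
#' @export
cv_space <- function(X, grid, folds) {
  K <- attr(folds, "K")
  fold_losses <- matrix(NA_real_, K, length(grid))
  for (k in seq_len(K)) {
    train <- X[folds != k, , drop = FALSE]
    test <- X[folds == k, , drop = FALSE]
    fits <- space_path(train, grid)
    fold_losses[k, ] <- vapply(fits, space_pred_error, numeric(1), Xtest = test)
  }
  new_cv_curve(grid, fold_losses)
}

#' BIC selection for SPACE
#'
#' Selects the penalty minimizing
#' \eqn{\sum_i \big( n\,\mathrm{RSS}_i(\hat\rho, \hat\omega_{ii}) + \kappa_i \log n \big)}
#' over the fitted path on the full sample, where \eqn{\mathrm{RSS}_i} is the
#' residual sum of squares of node i's joint regression and \eqn{\kappa_i}
#' its neighborhood size.
#'
#' @inheritParams cv_space
#' @param edge_tol Zero-detection tolerance on the partial correlations.
#' @return List with `lambda`, `criterion`, `fits` and `index`.
#' @export
bic_space <- function(X, grid, edge_tol = 1e-8) {
  n <- nrow(X)
  fits <- space_path(X, grid)
  crit <- vapply(fits, function(f) {
    kappa <- colSums(abs(f$rho) > edge_tol)  # rho has zero diagonal
    sum(n * f$rss + kappa * log(n))
  }, numeric(1))
  idx <- select_min_index(crit, grid)
  list(lambda = grid[idx], criterion = crit, fits = fits, index = idx)
}
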