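#' Graphical lasso for a fixed penalty
#'
#' Minimizes the penalized negative Gaussian log-likelihood
#' \deqn{\mathrm{tr}(S\Omega) - \log\det(\Omega) + \lambda_1 \sum_{i \ne j} |\omega_{ij}|}
#' over positive-definite precision matrices \eqn{\Omega}, by block
#' coordinate descent over columns (each column update is a lasso problem on
#' the current covariance estimate).  The diagonal is not penalized.
#'
#' @param S Sample covariance matrix (symmetric, positive diagonal).
#' @param lambda1 Positive penalty weight on the off-diagonal entries.
#' @param tol Convergence tolerance on the mean absolute change of the
#'   covariance iterate, relative to the mean absolute off-diagonal of `S`.
#' @param maxit Maximum number of full sweeps.
#' @param warm Optional fit returned by a previous call (warm start along a
#'   path).
#' @return Object of class `glasso_fit`: list with `omega` (precision
#'   estimate), `gamma` (partial correlations), `lambda1`, `loglik`
#'   (value of \eqn{\mathrm{tr}(S\Omega) - \log\det\Omega}), `objective`
#'   (penalized objective), `W`, `B` (internal state for warm starts),
#'   `converged`, `iterations`.
#' @examples
#' X <- sample_mvn(toy_model(), n = 200, seed = 1)
#' S <- crossprod(center_columns(X)) / nrow(X)
#' fit <- fit_glasso(S, lambda1 = 0.1)
#' edge_set(fit$gamma)
#' @export
fit_glasso <- function(S, lambda1, tol = 1e-6, maxit = 500, warm = NULL) {
  S <- as.matrix(S)
  check_square_symmetric(S, "S")
  if (any(diag(S) <= 0)) stop("S must have a strictly positive diagonal", call. = FALSE)
  if (lambda1 <= 0) stop("lambda1 must be positive", call. = FALSE)
  res <- glasso_cd(S, lambda1, tol, maxit,
                   if (is.null(warm)) NULL else warm$W,
                   if (is.null(warm)) NULL else warm$B)
  if (!res$converged) {
    warning(sprintf("glasso did not converge in %d sweeps (last change %.3g)",
                    maxit, res$delta))
  }
  omega <- res$omega
  nll <- sum(S * omega) - determinant_pd(omega)
  structure(list(omega = omega,
                 gamma = precision_to_partial(omega),
                 lambda1 = lambda1,
                 loglik = nll,
                 objective = nll + lambda1 * sum(abs(omega[row(omega) != col(omega)])),
                 W = res$W, B = res$B,
                 converged = res$converged, iterations = res$iterations),
            class = "glasso_fit")
}

# log-determinant via Cholesky; errors on non-PD input
determinant_pd <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) {
    stop("matrix is not positive definite", call. = FALSE)
  })
  2 * sum(log(diag(ch)))
}

#' Penalty grid for the graphical lasso
#'
#' 100 equidistant values from 0.001 (0.05 when `p >= 100`) up to the maximum
#' absolute entry of `S`.
#'
#' @param S Sample covariance matrix.
#' @param p Number of variables (defaults to `ncol(S)`).
#' @return Increasing numeric vector of length 100.
#' @export
glasso_grid <- function(S, p = ncol(S)) {
  lower <- if (p >= 100) 0.05 else 0.001
  upper <- max(abs(S))
  if (upper <= lower) stop("degenerate penalty grid: max|S| <= ", lower, call. = FALSE)
  seq(lower, upper, length.out = 100)
}

# Fit the whole glasso path (descending lambda, warm starts).  Returns a list
# of glasso_fit objects in grid (ascending) order.
glasso_path <- function(S, grid, tol = 1e-6, maxit = 500) {
  ord <- order(grid, decreasing = TRUE)
  fits <- vector("list", length(grid))
  warm <- NULL
  for (k in ord) {
    fit <- fit_glasso(S, grid[k], tol = tol, maxit = maxit, warm = warm)
    fits[[k]] <- fit
    warm <- fit
  }
  fits
}

#' Cross-validation curves for the graphical lasso
#'
#' Two K-fold cross-validation losses over a penalty grid.  For each fold the
#' precision matrix is re-estimated on the retained folds at every grid
#' value; the held-out fold contributes either the negative log-likelihood
#' \deqn{\mathrm{CV1}(\lambda_1) = \sum_k \{\mathrm{tr}(S^k \hat\Omega) - \log\det \hat\Omega\}}
#' with \eqn{S^k} the held-out sample covariance (fold-centered, 1/n_k
#' normalization), or the nodewise squared prediction error
#' \deqn{\mathrm{CV2}(\lambda_1) = \sum_k \sum_i \| X_i^k - \sum_{j \ne i} (-\hat\omega_{ij}/\hat\omega_{ii}) X_j^k \|^2.}
#'
#' @param X Centered data matrix.
#' @param grid Penalty grid (see [glasso_grid()]).
#' @param folds Fold assignment from [make_folds()].
#' @param loss `"loglik"` (CV1) or `"predict"` (CV2).
#' @return A `cv_curve` object (see [cv_select()]).
#' @export
cv_glasso <- function(X, grid, folds, loss = c("loglik", "predict")) {
  loss <- match.arg(loss)
  K <- attr(folds, "K")
  fold_losses <- matrix(NA_real_, K, length(grid))
  for (k in seq_len(K)) {
    train <- X[folds != k, , drop = FALSE]
    test <- X[folds == k, , drop = FALSE]
    if (nrow(test) < 2) stop("held-out fold has fewer than 2 rows", call. = FALSE)
    S_train <- crossprod(train) / nrow(train)
    fits <- glasso_path(S_train, grid)
    if (loss == "loglik") {
      test_c <- scale(test, center = TRUE, scale = FALSE)
      S_test <- crossprod(test_c) / nrow(test_c)
      fold_losses[k, ] <- vapply(fits, function(f) {
        sum(S_test * f$omega) - determinant_pd(f$omega)
      }, numeric(1))
    } else {
      fold_losses[k, ] <- vapply(fits, function(f) {
        pred_error_precision(f$omega, test)
      }, numeric(1))
    }
  }
  new_cv_curve(grid, fold_losses)
}

# sum over nodes of squared held-out prediction error using the regression
# weights -omega_ij / omega_ii implied by a precision matrix
pred_error_precision <- function(omega, Xtest) {
  d <- diag(omega)
  if (any(d == 0)) stop("invalid precision matrix: zero diagonal", call. = FALSE)
  B <- -sweep(omega, 1, d, "/")   # B[i, j] = -omega_ij / omega_ii
  diag(B) <- 0
  resid <- Xtest - Xtest %*% t(B)
  sum(resid^2)
}

#' Extended-BIC penalty term
#'
#' The model-complexity penalty
#' \eqn{\kappa \log n + 4 \kappa \gamma \log p} added to the deviance by the
#' extended Bayesian information criterion; `gamma = 0` gives the classical
#' BIC penalty.
#'
#' @param kappa Model size (non-zero parameter count).
#' @param n Sample count.
#' @param p Variable count.
#' @param gamma Extra penalization weight in `[0, 1]`.
#' @return Penalty value.
#' @export
ebic_penalty <- function(kappa, n, p, gamma = 0.5) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]", call. = FALSE)
  kappa * log(n) + 4 * kappa * gamma * log(p)
}

#' BIC / extended BIC selection for the graphical lasso
#'
#' Fits the path on the full-sample covariance and selects the penalty
#' minimizing
#' \deqn{\mathrm{EBIC}(\lambda_1) = -2\mathcal{L}(\hat\Omega) + \kappa \log n + 4 \kappa \gamma \log p,}
#' where \eqn{\mathcal{L} = (n/2)(\log\det\hat\Omega - \mathrm{tr}(S\hat\Omega))}
#' is the Gaussian log-likelihood and \eqn{\kappa} the number of non-zero
#' off-diagonal parameters of \eqn{\hat\Omega} (each edge contributes its
#' two symmetric entries).  `gamma = 0` is the classical BIC; the
#' recommended extended-BIC weight is `gamma = 0.5`.
#'
#' @param X Centered data matrix.
#' @param grid Penalty grid.
#' @param gamma Extra penalization weight in `[0, 1]`.
#' @param edge_tol Tolerance for counting edges.
#' @return List with `lambda` (selected value), `criterion` (per-grid EBIC),
#'   `fits` (the fitted path), and `index`.
#' @export
ebic_glasso <- function(X, grid, gamma = 0.5, edge_tol = 1e-8) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  S <- crossprod(X) / n
  fits <- glasso_path(S, grid)
  crit <- vapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    kappa <- 2 * nrow(edge_set(f$gamma, edge_tol))
    loglik <- (n / 2) * (determinant_pd(f$omega) - sum(S * f$omega))
    -2 * loglik + ebic_penalty(kappa, n, p, gamma)
  }, numeric(1))
  idx <- select_min_index(crit, grid)
  list(lambda = grid[idx], criterion = crit, fits = fits, index = idx)
}
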