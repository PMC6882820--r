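#' Penalty grid for a single nodewise regression
#'
#' Reproduces the grid construction of the glmnet software on the unscaled
#' nodewise objective: the largest value is
#' \eqn{\lambda_{\max} = \max_j |X_j' X_i|}, the smallest value at which all
#' regression weights of node `i` are zero, and 100 log-equidistant values
#' descend to `ratio * lambda_max` with `ratio = 1e-4` when `n > p` and
#' `0.01` otherwise.
#'
#' @param X Centered data matrix.
#' @param node Index of the response variable.
#' @return Increasing numeric vector of length 100.
#' @export
nodewise_grid <- function(X, node) {
  n <- nrow(X)
  p <- ncol(X)
  y <- X[, node]
  if (stats::sd(y) == 0) stop("zero-variance response column", call. = FALSE)
  lambda_max <- max(abs(crossprod(X[, -node, drop = FALSE], y)))
  ratio <- if (n > p) 1e-4 else 1e-2
  exp(seq(log(lambda_max * ratio), log(lambda_max), length.out = 100))
}

# Lasso path for one node at the penalties in `grid` (unscaled objective
# 0.5*RSS + lambda*|beta|_1).  glmnet solves (1/2n)*RSS + lambda*|beta|_1, so
# penalties are rescaled by 1/n.  Returns a (p-1) x length(grid) matrix of
# weights, columns in grid order.  The p = 2 single-predictor case is the
# exact soft-threshold solution.
lasso_path_node <- function(X, node, grid) {
  n <- nrow(X)
  y <- X[, node]
  Xo <- X[, -node, drop = FALSE]
  if (ncol(Xo) == 1) {
    xy <- sum(Xo * y)
    xx <- sum(Xo^2)
    return(matrix(vapply(grid, function(l) soft_thresh(xy, l) / xx, numeric(1)),
                  nrow = 1))
  }
  ord <- order(grid, decreasing = TRUE)
  fit <- glmnet::glmnet(Xo, y, family = "gaussian",
                        lambda = grid[ord] / n,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-10)
  coefs <- as.matrix(fit$beta)
  out <- matrix(0, ncol(Xo), length(grid))
  out[, ord] <- coefs
  out
}

soft_thresh <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Nodewise lasso estimation of a sparse partial correlation network
#'
#' Performs the p separate lasso regressions
#' \deqn{\hat\beta_i(\lambda_2) = \arg\min_{\beta} \tfrac12 \|X_i - \textstyle\sum_{j\ne i} \beta_{ij} X_j\|^2 + \lambda_2 \textstyle\sum_{j \ne i} |\beta_{ij}|}
#' and reconciles the two weights per pair into an edge with the AND rule
#' (both non-zero) or the OR rule (at least one non-zero).  Partial
#' correlations come from the geometric-mean relation
#' (see [regression_to_partial()]) restricted to the selected edges.
#'
#' @param X Centered data matrix.
#' @param lambda2 Positive penalty, a scalar or one value per node.
#' @param rule Edge rule, `"and"` or `"or"`.
#' @param edge_tol Zero-detection tolerance on the weights.
#' @return Object of class `nodewise_fit`: `beta` (p x p weights, zero
#'   diagonal), `resid_var`, `lambda2`, `rule`, `edges` (an `edge_set`), and
#'   `gamma` (partial correlations supported on the selected edges).
#' @export
fit_nodewise_lasso <- function(X, lambda2, rule = c("and", "or"),
                               edge_tol = 1e-8) {
  rule <- match.arg(rule)
  n <- nrow(X)
  p <- ncol(X)
  lambda2 <- rep_len(lambda2, p)
  if (any(lambda2 <= 0)) stop("lambda2 must be positive", call. = FALSE)
  beta <- matrix(0, p, p)
  resid_var <- numeric(p)
  for (i in seq_len(p)) {
    lmax <- max(abs(crossprod(X[, -i, drop = FALSE], X[, i])))
    path <- if (lambda2[i] >= lmax) {
      matrix(0, p - 1, 1)
    } else {
      # short warm-started descent ending exactly at the requested penalty
      g <- exp(seq(log(lambda2[i]), log(lmax), length.out = 20))
      lasso_path_node(X, i, g)[, 1, drop = FALSE]
    }
    beta[i, -i] <- path[, 1]
    resid_var[i] <- sum((X[, i] - X[, -i, drop = FALSE] %*% path[, 1])^2) / n
  }
  nodewise_network(X, beta, resid_var, lambda2, rule, edge_tol)
}

# assemble the fit object from a weight matrix
nodewise_network <- function(X, beta, resid_var, lambda, rule, edge_tol) {
  p <- ncol(X)
  nz <- abs(beta) > edge_tol
  sel <- if (rule == "and") nz & t(nz) else nz | t(nz)
  edges <- edge_set(1 * (sel & upper.tri(sel) | t(sel & upper.tri(sel))), 0.5)
  gamma <- regression_to_partial(beta)
  mask <- matrix(FALSE, p, p)
  if (nrow(edges) > 0) {
    mask[edges] <- TRUE
    mask[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  gamma[!mask & row(gamma) != col(gamma)] <- 0
  structure(list(beta = beta, resid_var = resid_var, lambda2 = lambda,
                 rule = rule, edges = edges, gamma = gamma),
            class = "nodewise_fit")
}

#' Cross-validation curve for one nodewise regression
#'
#' K-fold held-out squared prediction error
#' \deqn{\mathrm{CV}(\lambda) = \sum_k \|X_i^k - \textstyle\sum_{j\ne i} \hat\beta_{ij} X_j^k\|^2}
#' with the weights refit on the retained folds at every grid value, for the
#' lasso (`penalty = "lasso"`) or ridge (`penalty = "ridge"`) nodewise
#' objective.
#'
#' @param X Centered data matrix.
#' @param node Response variable index.
#' @param grid Penalty grid (see [nodewise_grid()]).
#' @param folds Fold assignment from [make_folds()].
#' @param penalty `"lasso"` or `"ridge"`.
#' @return A `cv_curve` object.
#' @export
cv_nodewise <- function(X, node, grid, folds, penalty = c("lasso", "ridge")) {
  penalty <- match.arg(penalty)
  K <- attr(folds, "K")
  fold_losses <- matrix(NA_real_, K, length(grid))
  for (k in seq_len(K)) {
    train <- X[folds != k, , drop = FALSE]
    test <- X[folds == k, , drop = FALSE]
    path <- if (penalty == "lasso") {
      lasso_path_node(train, node, grid)
    } else {
      ridge_path_node(train, node, grid)
    }
    pred <- test[, -node, drop = FALSE] %*% path
    fold_losses[k, ] <- colSums((test[, node] - pred)^2)
  }
  new_cv_curve(grid, fold_losses)
}

#' BIC selection for one nodewise lasso regression
#'
#' Selects the penalty minimizing
#' \eqn{\mathrm{BIC}_i(\lambda_2) = n\,\mathrm{RSS}(\hat\beta_i) + \kappa_i \log n},
#' with RSS the residual sum of squares of the regression of node `i` and
#' \eqn{\kappa_i} its neighborhood size, evaluated over the fitted path on
#' the full sample.
#'
#' @inheritParams cv_nodewise
#' @param edge_tol Zero-detection tolerance on the weights.
#' @return List with `lambda`, `criterion` and `index`.
#' @export
bic_nodewise <- function(X, node, grid, edge_tol = 1e-8) {
  n <- nrow(X)
  path <- lasso_path_node(X, node, grid)
  resid <- X[, node] - X[, -node, drop = FALSE] %*% path
  rss <- colSums(resid^2)
  kappa <- colSums(abs(path) > edge_tol)
  crit <- n * rss + kappa * log(n)
  idx <- select_min_index(crit, grid)
  list(lambda = grid[idx], criterion = crit, index = idx)
}

# Exact ridge path for one node: delta = (X'X + 2 lambda I)^{-1} X'y, the
# minimizer of 0.5*RSS + lambda*|delta|^2, computed for all penalties from
# one eigendecomposition.
ridge_path_node <- function(X, node, grid) {
  Xo <- X[, -node, drop = FALSE]
  y <- X[, node]
  eg <- eigen(crossprod(Xo), symmetric = TRUE)
  uty <- crossprod(eg$vectors, crossprod(Xo, y))
  out <- vapply(grid, function(l) {
    drop(eg$vectors %*% (uty / (eg$values + 2 * l)))
  }, numeric(ncol(Xo)))
  matrix(out, ncol = length(grid))
}

#' Nodewise ridge estimation of a dense partial correlation network
#'
#' Performs the p separate ridge regressions
#' \deqn{\hat\delta_i(\lambda_4) = \arg\min_\delta \tfrac12\|X_i - \textstyle\sum_{j\ne i}\delta_{ij}X_j\|^2 + \lambda_4 \textstyle\sum_{j\ne i} \delta_{ij}^2,}
#' solved exactly as \eqn{\hat\delta_i = (X_{-i}'X_{-i} + 2\lambda_4 I)^{-1} X_{-i}'X_i}.
#' Ridge weights are never exactly zero, so the resulting network is dense by
#' construction; its value lies in the partial correlations fed to the
#' screening stage.
#'
#' @param X Centered data matrix.
#' @param lambda4 Positive penalty, a scalar or one value per node.
#' @param edge_tol Zero-detection tolerance on the weights.
#' @return Object of class `nodewise_fit` with `delta` weights in `beta`;
#'   `edges` holds every pair with both weights above `edge_tol` (in practice
#'   all pairs).
#' @export
fit_ridge_nodewise <- function(X, lambda4, edge_tol = 1e-8) {
  n <- nrow(X)
  p <- ncol(X)
  lambda4 <- rep_len(lambda4, p)
  if (any(lambda4 < 0)) stop("lambda4 must be non-negative", call. = FALSE)
  beta <- matrix(0, p, p)
  resid_var <- numeric(p)
  for (i in seq_len(p)) {
    if (lambda4[i] == 0 && n <= p - 1) {
      stop("unpenalized ridge system is rank deficient (n <= p - 1)", call. = FALSE)
    }
    d <- ridge_path_node(X, i, lambda4[i])[, 1]
    beta[i, -i] <- d
    resid_var[i] <- sum((X[, i] - X[, -i, drop = FALSE] %*% d)^2) / n
  }
  fit <- nodewise_network(X, beta, resid_var, lambda4, rule = "and", edge_tol)
  names(fit)[names(fit) == "lambda2"] <- "lambda4"
  fit
}
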