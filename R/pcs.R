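#' Threshold grid for partial correlation screening
#'
#' 100 equidistant candidate thresholds from 0.0001 to 1.
#'
#' @param size Grid length.
#' @return Increasing numeric vector.
#' @export
tau_grid <- function(size = 100) seq(1e-4, 1, length.out = size)

#' Screen a partial correlation matrix at a threshold
#'
#' Keeps the pairs whose estimated partial correlation strictly exceeds the
#' threshold in absolute value:
#' \eqn{\hat E_\tau = \{(i,j) : |\hat\rho_{ij|V\setminus\{i,j\}}| > \tau\}}.
#' The result is always a subset of the support of the input.
#'
#' @param gamma Estimated partial correlation matrix from any first-stage
#'   estimator.
#' @param tau Threshold in (0, 1).
#' @return An `edge_set` of retained pairs.
#' @export
screen_edges <- function(gamma, tau) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)", call. = FALSE)
  edge_set(gamma, tol = tau)
}

# per-node neighborhoods (index vectors) implied by an edge set
edge_neighborhoods <- function(edges, p) {
  nb <- rep(list(integer(0)), p)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, sort)
}

# least-squares coefficients of y on Xa; minimum-norm solution (flagged via
# attribute) when the system is rank deficient or over-saturated
ols_coef <- function(Xa, y) {
  if (ncol(Xa) == 0) return(numeric(0))
  qr_d <- qr(Xa)
  if (qr_d$rank == ncol(Xa)) {
    drop(qr.coef(qr_d, y))
  } else {
    sv <- svd(Xa)
    pos <- sv$d > max(sv$d) * 1e-12
    theta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    structure(drop(theta), min_norm = TRUE)
  }
}

#' OLS refit on screened neighborhoods
#'
#' For each node i, regresses \eqn{X_i} by ordinary least squares on the
#' variables in its screened neighborhood \eqn{\hat{A}_{i,\tau}}; an empty
#' neighborhood yields a zero prediction, so the residual is \eqn{X_i}
#' itself.  Over-saturated systems (neighborhood size at or above the row
#' count) fall back to the minimum-norm least-squares solution.
#'
#' @param X Centered data matrix.
#' @param neighborhoods List of per-node index vectors.
#' @return List with `theta` (p x p weight matrix, `theta[i, j]` the weight
#'   of variable j in node i's refit, zero outside the neighborhood),
#'   `residuals` (n x p matrix), `rss` (per-node residual sums of squares)
#'   and `min_norm` (logical per node).
#' @export
refit_ols <- function(X, neighborhoods) {
  n <- nrow(X)
  p <- ncol(X)
  theta <- matrix(0, p, p)
  resid <- X
  min_norm <- logical(p)
  for (i in seq_len(p)) {
    nb <- neighborhoods[[i]]
    if (length(nb) == 0) next
    th <- ols_coef(X[, nb, drop = FALSE], X[, i])
    min_norm[i] <- isTRUE(attr(th, "min_norm"))
    theta[i, nb] <- th
    resid[, i] <- X[, i] - X[, nb, drop = FALSE] %*% as.numeric(th)
  }
  list(theta = theta, residuals = resid, rss = colSums(resid^2),
       min_norm = min_norm)
}

#' Cross-validated selection of the screening threshold
#'
#' Implements the double-loop threshold selection: the regularization
#' penalty `lambda` has already been selected on the full sample (outer
#' loop); here, for each fold, the first-stage network is re-estimated on
#' the retained folds at that fixed penalty, and for every candidate
#' threshold the neighborhoods are screened, refit by OLS on the same
#' training folds, and scored on the held-out fold:
#' \deqn{\mathrm{CV}(\tau) = \sum_{k=1}^K \sum_{i=1}^p \Big\| X_i^k - \sum_{j \in \hat{A}_{i,\tau}} \hat\theta_{ij,\tau} X_j^k \Big\|^2.}
#' The loss is piecewise constant in \eqn{\tau} (breakpoints at the sorted
#' absolute partial correlations of the per-fold networks), so each distinct
#' edge set is refit only once.  Ties in the argmin go to the largest
#' threshold (sparser final network).
#'
#' @param X Centered data matrix.
#' @param method First-stage estimator (see [estimate_network()]).
#' @param lambda Penalty selected on the full sample (scalar or per node).
#' @param folds Fold assignment from [make_folds()].
#' @param grid Candidate thresholds (default [tau_grid()]).
#' @param edge_tol First-stage zero-detection tolerance.
#' @return List with `tau` (selected threshold), `curve` (a `cv_curve` over
#'   the threshold grid) and `degenerate` (`TRUE` when every per-fold
#'   network was empty, in which case the smallest threshold is returned
#'   with a warning).
#' @export
select_tau <- function(X, method, lambda, folds, grid = tau_grid(),
                       edge_tol = 1e-8) {
  K <- attr(folds, "K")
  p <- ncol(X)
  fold_losses <- matrix(NA_real_, K, length(grid))
  any_edges <- FALSE
  for (k in seq_len(K)) {
    train <- X[folds != k, , drop = FALSE]
    test <- X[folds == k, , drop = FALSE]
    gamma_k <- fit_at_lambda(train, method, lambda, edge_tol = edge_tol)$gamma
    offdiag <- abs(gamma_k[upper.tri(gamma_k)])
    if (any(offdiag > grid[1])) any_edges <- TRUE
    # group thresholds by the edge set they induce (nested in tau)
    counts <- vapply(grid, function(t) sum(offdiag > t), integer(1))
    for (cnt in unique(counts)) {
      idx <- which(counts == cnt)
      tau_rep <- grid[idx[1]]
      nb <- edge_neighborhoods(screen_edges(gamma_k, tau_rep), p)
      refit <- refit_ols(train, nb)
      pred <- test %*% t(refit$theta)
      fold_losses[k, idx] <- sum((test - pred)^2)
    }
  }
  curve <- new_cv_curve(grid, fold_losses)
  if (!any_edges) {
    warning("every cross-validation network is empty at all thresholds; ",
            "returning the smallest threshold")
    return(list(tau = grid[1], curve = curve, degenerate = TRUE))
  }
  idx <- select_min_index(curve$loss, grid)
  list(tau = grid[idx], curve = curve, degenerate = FALSE)
}

#' Partial correlation screening (PCS) pipeline
#'
#' Two-stage estimation of a sparse partial correlation network: (1) tune
#' and fit one of the base estimators on the full sample; (2) select a
#' screening threshold by K-fold cross-validation ([select_tau()]), drop all
#' edges whose estimated partial correlation does not exceed it in absolute
#' value, and refit the surviving neighborhoods by OLS.  Screening never
#' adds edges, so the final network is a subset of the first-stage one; an
#' empty first-stage network is returned unchanged (false negatives cannot
#' be repaired by screening).
#'
#' @inheritParams estimate_network
#' @param tau_grid_size Length of the threshold grid.
#' @param network Optionally, an already-fitted `ggm_network` (then `X`,
#'   `method` and `tuning` are taken from it and the remaining arguments are
#'   ignored).
#' @return Object of class `pcs_network`: `tau` (selected threshold, `NA`
#'   when screening was skipped), `edges` (final `edge_set`), `gamma`
#'   (screened partial correlations), `theta` (OLS refit weights),
#'   `residuals`, `neighborhoods`, `tau_curve`, and `first_stage` (the
#'   underlying `ggm_network`).
#' @examples
#' X <- sample_mvn(toy_model(), n = 100, seed = 3)
#' fit <- pcs(X, method = "glasso", tuning = "cv2", seed = 3)
#' fit$edges
#' @export
pcs <- function(X, method = METHODS, tuning = "cv", folds = 10, seed = 1,
                gamma = 0.5, alpha = 0.05, edge_tol = 1e-8,
                standardize = FALSE, tau_grid_size = 100, network = NULL) {
  net <- if (is.null(network)) {
    estimate_network(X, method, tuning, folds = folds, seed = seed,
                     gamma = gamma, alpha = alpha, edge_tol = edge_tol,
                     standardize = standardize)
  } else {
    stopifnot(inherits(network, "ggm_network"))
    network
  }
  p <- ncol(net$gamma)
  if (nrow(net$edges) == 0) {
    # nothing to screen: an empty network is returned unchanged
    return(structure(list(tau = NA_real_, edges = net$edges,
                          gamma = net$gamma,
                          theta = matrix(0, p, p),
                          residuals = net$X, neighborhoods = rep(list(integer(0)), p),
                          tau_curve = NULL, first_stage = net),
                     class = "pcs_network"))
  }
  sel <- select_tau(net$X, net$method, net$lambda, net$folds,
                    grid = tau_grid(tau_grid_size), edge_tol = net$edge_tol)
  edges <- screen_edges(net$gamma, sel$tau)
  nb <- edge_neighborhoods(edges, p)
  refit <- refit_ols(net$X, nb)
  gamma_screened <- net$gamma
  mask <- matrix(FALSE, p, p)
  if (nrow(edges) > 0) {
    mask[edges] <- TRUE
    mask[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  gamma_screened[!mask & row(gamma_screened) != col(gamma_screened)] <- 0
  structure(list(tau = sel$tau, edges = edges, gamma = gamma_screened,
                 theta = refit$theta, residuals = refit$residuals,
                 neighborhoods = nb, tau_curve = sel$curve,
                 first_stage = net),
            class = "pcs_network")
}

#' @exportS3Method base::print
print.pcs_network <- function(x, ...) {
  fs <- x$first_stage
  cat(sprintf("pcs_network: %s-%s + screening, tau = %s\n",
              fs$method, fs$tuning,
              if (is.na(x$tau)) "(skipped)" else format(x$tau, digits = 4)))
  cat(sprintf("  first stage: %d edges -> screened: %d edges\n",
              nrow(fs$edges), nrow(x$edges)))
  invisible(x)
}
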