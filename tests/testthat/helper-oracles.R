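# Independent oracles used across the test files.  These deliberately avoid
# the code paths they certify: partial correlations through Schur
# complements, glasso optimality through a duality-gap certificate, SPACE
# and ridge through generic numeric optimization of the written objectives.

random_spd <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(p)
}

# population partial correlation of (i, j) given the rest, via the
# conditional (Schur-complement) covariance of the pair -- equivalently the
# correlation of the residuals of the best linear predictors of X_i and X_j
# on the remaining variables
partial_cor_schur <- function(sigma, i, j) {
  rest <- setdiff(seq_len(ncol(sigma)), c(i, j))
  C <- sigma[c(i, j), c(i, j)] -
    sigma[c(i, j), rest, drop = FALSE] %*%
    solve(sigma[rest, rest, drop = FALSE], sigma[rest, c(i, j), drop = FALSE])
  C[1, 2] / sqrt(C[1, 1] * C[2, 2])
}

glasso_primal <- function(S, omega, lambda) {
  sum(S * omega) - as.numeric(determinant(omega, logarithm = TRUE)$modulus) +
    lambda * sum(abs(omega[row(omega) != col(omega)]))
}

# duality-gap certificate for the penalized likelihood problem: project
# solve(omega) into the dual-feasible box {|theta_ij - S_ij| <= lambda,
# theta_ii = S_ii}; the gap between the primal objective and the dual
# objective logdet(theta) + p bounds the suboptimality of omega
glasso_duality_gap <- function(S, omega, lambda) {
  theta <- solve(omega)
  off <- row(theta) != col(theta)
  theta[off] <- pmin(pmax(theta[off], S[off] - lambda), S[off] + lambda)
  diag(theta) <- diag(S)
  dual <- as.numeric(determinant(theta, logarithm = TRUE)$modulus) + nrow(S)
  glasso_primal(S, omega, lambda) - dual
}

# the joint sparse regression objective, written directly from its formula
space_objective_r <- function(X, rho, w, lambda) {
  p <- ncol(X)
  rss <- 0
  for (i in seq_len(p)) {
    pred <- rep(0, nrow(X))
    for (j in seq_len(p)) {
      if (j != i) pred <- pred + rho[i, j] * sqrt(w[j] / w[i]) * X[, j]
    }
    rss <- rss + sum((X[, i] - pred)^2)
  }
  rss / 2 + lambda * sum(abs(rho[upper.tri(rho)]))
}

ridge_objective_r <- function(X, node, delta, lambda) {
  resid <- X[, node] - X[, -node, drop = FALSE] %*% delta
  sum(resid^2) / 2 + lambda * sum(delta^2)
}

# straightforward re-evaluation of the threshold cross-validation loss,
# recomputing every grid value from scratch (no breakpoint grouping)
naive_tau_losses <- function(X, method, lambda, folds, grid) {
  K <- attr(folds, "K")
  p <- ncol(X)
  loss <- numeric(length(grid))
  for (k in seq_len(K)) {
    train <- X[folds != k, , drop = FALSE]
    test <- X[folds == k, , drop = FALSE]
    gamma_k <- pcsnet:::fit_at_lambda(train, method, lambda)$gamma
    for (t in seq_along(grid)) {
      edges <- screen_edges(gamma_k, grid[t])
      nb <- pcsnet:::edge_neighborhoods(edges, p)
      fold_loss <- 0
      for (i in seq_len(p)) {
        if (length(nb[[i]]) == 0) {
          fold_loss <- fold_loss + sum(test[, i]^2)
        } else {
          th <- qr.coef(qr(train[, nb[[i]], drop = FALSE]), train[, i])
          fold_loss <- fold_loss +
            sum((test[, i] - test[, nb[[i]], drop = FALSE] %*% th)^2)
        }
      }
      loss[t] <- loss[t] + fold_loss
    }
  }
  loss
}

edge_pairs <- function(e) unname(cbind(e[, 1], e[, 2]))

edge_key <- function(e) pcsnet:::edge_key(e)

expect_same_edges <- function(a, b) {
  expect_identical(edge_pairs(a), edge_pairs(b))
}
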