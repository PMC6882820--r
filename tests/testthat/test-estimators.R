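test_that("glasso at full shrinkage is diagonal and matches the p=2 closed form", {
  S <- random_spd(5, seed = 11)
  fit <- fit_glasso(S, lambda1 = max(abs(S)) + 1)
  expect_equal(nrow(edge_set(fit$gamma)), 0)
  expect_equal(diag(fit$omega), 1 / diag(S), tolerance = 1e-8)

  # p = 2: the solution is the inverse of S with the off-diagonal soft
  # thresholded toward zero by lambda
  s <- 0.6; lam <- 0.25
  S2 <- matrix(c(1, s, s, 1), 2)
  fit2 <- fit_glasso(S2, lam, tol = 1e-9)
  expected <- solve(matrix(c(1, s - lam, s - lam, 1), 2))
  expect_equal(fit2$omega, expected, tolerance = 1e-6)
})

test_that("glasso solutions satisfy a duality-gap optimality certificate", {
  for (seed in c(21, 22)) {
    S <- random_spd(4, seed = seed)
    fit <- fit_glasso(S, 0.1, tol = 1e-9)
    expect_lt(glasso_duality_gap(S, fit$omega, 0.1), 1e-5)
    expect_gt(min(eigen(fit$omega, only.values = TRUE)$values), 0)
  }
})

test_that("glasso approaches the inverse sample covariance as the penalty vanishes", {
  S <- random_spd(5, seed = 31)
  fit <- fit_glasso(S, 1e-7, tol = 1e-9)
  expect_lt(norm(fit$omega - solve(S), "F"), 1e-4)
})

test_that("l1 estimators have non-increasing edge counts along the penalty grid", {
  X <- center_columns(sample_mvn(chain_model(8), n = 60, seed = 41))
  S <- crossprod(X) / nrow(X)
  grid <- glasso_grid(S, 8)[seq(1, 100, by = 9)]
  counts <- vapply(pcsnet:::glasso_path(S, grid),
                   function(f) nrow(edge_set(f$gamma)), integer(1))
  expect_true(all(diff(counts) <= 0) || all(diff(rev(counts)) >= 0))
  expect_true(all(diff(counts) <= 0))

  sgrid <- space_grid(60, 8)[seq(1, 100, by = 9)]
  scounts <- vapply(pcsnet:::space_path(X, sgrid),
                    function(f) nrow(edge_set(f$rho)), integer(1))
  expect_true(all(diff(scounts) <= 0))
})

test_that("nodewise lasso matches the soft-threshold solution and the edge rules", {
  m <- toy_model()
  X <- center_columns(sample_mvn(m, 50, seed = 51))
  # full shrinkage: no weight survives a penalty above every inner product
  lmax <- max(abs(crossprod(X)[row(diag(6)) != col(diag(6))]))
  fit0 <- fit_nodewise_lasso(X, lmax + 1, rule = "or")
  expect_true(all(fit0$beta == 0))
  expect_equal(nrow(fit0$edges), 0)

  # p = 2 single-predictor case: exact soft threshold of the OLS normal
  # equation
  X2 <- X[, 1:2]
  lam <- 0.3 * abs(sum(X2[, 1] * X2[, 2]))
  fit2 <- fit_nodewise_lasso(X2, lam)
  expected <- sign(sum(X2[, 1] * X2[, 2])) *
    (abs(sum(X2[, 1] * X2[, 2])) - lam) / sum(X2[, 2]^2)
  expect_equal(fit2$beta[1, 2], expected, tolerance = 1e-10)

  # AND vs OR on an asymmetric support
  beta <- matrix(0, 3, 3); beta[1, 2] <- 0.4
  fit_and <- pcsnet:::nodewise_network(X[, 1:3], beta, rep(1, 3), 1, "and", 1e-8)
  fit_or <- pcsnet:::nodewise_network(X[, 1:3], beta, rep(1, 3), 1, "or", 1e-8)
  expect_equal(nrow(fit_and$edges), 0)
  expect_same_edges(fit_or$edges, pcsnet:::new_edge_set(cbind(1, 2), 3))
})

test_that("SPACE matches a generic numeric optimizer at lambda = 0", {
  X <- center_columns(sample_mvn(chain_model(3), n = 50, seed = 61))
  fit <- fit_space(X, lambda3 = 0, tol = 1e-9, max_outer = 200)

  obj_fn <- function(par) {
    rho <- diag(3) * 0
    rho[1, 2] <- rho[2, 1] <- par[1]
    rho[1, 3] <- rho[3, 1] <- par[2]
    rho[2, 3] <- rho[3, 2] <- par[3]
    space_objective_r(X, rho, exp(par[4:6]), 0)
  }
  opt <- optim(c(0, 0, 0, 0, 0, 0), obj_fn, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  ours <- space_objective_r(X, fit$rho, fit$omega_diag, 0)
  expect_lt(ours - opt$value, 1e-4)
})

test_that("SPACE full shrinkage and objective decrease hold", {
  X <- center_columns(sample_mvn(chain_model(6), n = 80, seed = 71))
  big <- max(space_grid(80, 6))
  fit <- fit_space(X, big * 10)
  expect_equal(fit$rho, matrix(0, 6, 6))
  expect_equal(fit$gamma, diag(6))

  lam <- min(space_grid(80, 6))
  fit2 <- fit_space(X, lam)
  init_obj <- space_objective_r(X, matrix(0, 6, 6),
                                1 / apply(X, 2, var), lam)
  expect_lte(fit2$objective, init_obj)
  expect_equal(fit2$objective,
               space_objective_r(X, fit2$rho, fit2$omega_diag, lam),
               tolerance = 1e-8)
})

test_that("SPACE recovers the chain pattern from a large sample", {
  m <- chain_model(10, neighbors = 1)
  X <- center_columns(sample_mvn(m, 5000, seed = 81))
  fit <- fit_space(X, lambda3 = min(space_grid(5000, 10)))
  expect_lt(max(abs(fit$gamma - m$gamma)), 0.05)
})

test_that("ridge matches its closed form, a numeric optimizer, and its limits", {
  X <- center_columns(sample_mvn(chain_model(5), n = 100, seed = 91))
  fit <- fit_ridge_nodewise(X, 1)
  # generic numeric optimizer of the written objective, node 1
  opt <- optim(rep(0, 4), function(d) ridge_objective_r(X, 1, d, 1),
               method = "BFGS", control = list(reltol = 1e-15, maxit = 5000))
  expect_equal(unname(fit$beta[1, -1]), opt$par, tolerance = 1e-6)

  # unpenalized limit equals OLS
  fit0 <- fit_ridge_nodewise(X, 1e-12)
  ols <- qr.coef(qr(X[, -1]), X[, 1])
  expect_equal(unname(fit0$beta[1, -1]), unname(ols), tolerance = 1e-6)

  # infinite shrinkage drives every weight to zero
  fit_inf <- fit_ridge_nodewise(X, 1e9)
  expect_lt(max(abs(fit_inf$beta)), 1e-6)

  # dense network on continuous data
  expect_equal(nrow(fit$edges), choose(5, 2))
})
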