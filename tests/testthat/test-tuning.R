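test_that("penalty grids have the stated endpoints, lengths and scaling", {
  S <- toy_model()$sigma
  g <- glasso_grid(S, p = 6)
  expect_length(g, 100)
  expect_equal(g[1], 0.001)
  expect_equal(g[100], max(abs(S)))  # 1.68, the largest absolute entry
  expect_equal(diff(g), rep((max(abs(S)) - 0.001) / 99, 99))
  expect_true(all(diff(g) > 0))
  expect_equal(glasso_grid(S, p = 150)[1], 0.05)

  sg <- space_grid(100, 20)
  expect_length(sg, 100)
  expect_equal(sg[1], sqrt(100) * qnorm(1 - 0.9 / (2 * 20^2)))
  expect_equal(sg[100], sqrt(100) * qnorm(1 - 1e-4 / (2 * 20^2)))
  expect_equal(space_grid(400, 20) / sg, rep(2, 100))  # sqrt(n) scaling
  for (n in c(2, 10, 1000)) for (p in c(2, 5, 50)) {
    expect_gt(space_grid(n, p)[100], space_grid(n, p)[1])
  }
})

test_that("nodewise grid tops out at the smallest all-zero penalty", {
  X <- center_columns(sample_mvn(toy_model(), 40, seed = 5))
  g <- nodewise_grid(X, node = 1)
  expect_length(g, 100)
  lmax_brute <- max(abs(crossprod(X[, -1], X[, 1])))
  expect_equal(g[100], lmax_brute)
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 99))  # log-equidistant
  # all weights zero exactly at lambda_max, some nonzero just below
  fit_at <- fit_nodewise_lasso(X, g[100], rule = "or")
  expect_true(all(fit_at$beta[1, ] == 0))
  path <- pcsnet:::lasso_path_node(X, 1, g)
  expect_true(any(path[, 50] != 0))
})

test_that("fold assignment is balanced and reproducible", {
  f <- make_folds(47, K = 10, seed = 3)
  expect_true(all(table(f) %in% c(4, 5)))
  expect_identical(as.integer(f), as.integer(make_folds(47, 10, seed = 3)))
  expect_false(identical(as.integer(f), as.integer(make_folds(47, 10, seed = 4))))
  expect_error(make_folds(5, K = 6), "K <= n")
})

test_that("cv_select implements the minimum and one-standard-error rules", {
  # strictly convex curve: unique argmin
  grid <- c(0.1, 0.2, 0.3)
  curve <- pcsnet:::new_cv_curve(grid, rbind(c(5, 1, 4), c(5, 1, 4)))
  expect_equal(cv_select(curve, "min")$lambda, 0.2)

  # hand-computed one-standard-error rule, K = 2:
  # losses: 10, 8, 9; fold losses at the argmin 3 and 5 ->
  # sd = sqrt(2), se = 1; threshold 9 admits lambda = 0.3
  curve2 <- pcsnet:::new_cv_curve(grid, rbind(c(5, 3, 4), c(5, 5, 5)))
  expect_equal(curve2$loss, c(10, 8, 9))
  sel <- cv_select(curve2, "one_se")
  expect_equal(sel$se, sd(c(3, 5)) / sqrt(2))
  expect_equal(sel$lambda, 0.3)

  # flat curve: the most regularized value wins under both rules
  flat <- pcsnet:::new_cv_curve(grid, rbind(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(cv_select(flat, "min")$lambda, 0.3)
  expect_equal(cv_select(flat, "one_se")$lambda, 0.3)
})

test_that("one-standard-error selection is never less regularized than the minimum rule", {
  X <- sample_mvn(chain_model(6), 80, seed = 17)
  net_min <- estimate_network(X, "space", "cv", seed = 17)
  net_1se <- estimate_network(X, "space", "cv_1se", seed = 17)
  expect_gte(net_1se$lambda, net_min$lambda)
  for (seed in c(1, 2)) {
    curve <- cv_nodewise(center_columns(X), 1, nodewise_grid(center_columns(X), 1),
                         make_folds(80, 10, seed))
    expect_gte(cv_select(curve, "one_se")$lambda, cv_select(curve, "min")$lambda)
  }
})

test_that("glasso cross-validation losses behave as the formulas dictate", {
  m <- toy_model()
  X <- center_columns(sample_mvn(m, 100, seed = 23))
  folds <- make_folds(100, 10, seed = 23)

  # a diagonal precision fit predicts zero for every node, so the
  # prediction-error loss is the total sum of squares of the held-out data
  big <- max(abs(crossprod(X) / 100)) + 1
  curve <- cv_glasso(X, c(big, big + 1), folds, loss = "predict")
  expect_equal(curve$loss, rep(sum(X^2), 2), tolerance = 1e-6)
  expect_true(all(curve$fold_losses >= 0))

  # single-value grid: selection returns that value
  one <- cv_glasso(X, 0.2, folds, loss = "loglik")
  expect_equal(cv_select(one, "min")$lambda, 0.2)

  # p = 2 worked instance of the prediction loss with weights
  # -omega_12/omega_11
  omega <- matrix(c(2, -0.5, -0.5, 1), 2)
  Xt <- matrix(c(1, -1, 2, 0.5, 1, -2), 3, 2)
  manual <- sum((Xt[, 1] - (-(-0.5) / 2) * Xt[, 2])^2) +
    sum((Xt[, 2] - (-(-0.5) / 1) * Xt[, 1])^2)
  expect_equal(pcsnet:::pred_error_precision(omega, Xt), manual)
})

test_that("extended BIC reduces to BIC at gamma zero and is never denser at 0.5", {
  expect_equal(ebic_penalty(2, n = 100, p = 5, gamma = 0.5),
               2 * log(100) + 4 * 2 * 0.5 * log(5))
  expect_equal(ebic_penalty(7, n = 50, p = 9, gamma = 0),
               7 * log(50))

  X <- center_columns(sample_mvn(chain_model(8), 120, seed = 29))
  grid <- glasso_grid(crossprod(X) / 120, 8)[seq(5, 100, by = 10)]
  bic_sel <- ebic_glasso(X, grid, gamma = 0)
  ebic_sel <- ebic_glasso(X, grid, gamma = 0.5)
  # gamma = 0 is definitionally the classical BIC criterion
  kappa <- vapply(bic_sel$fits, function(f) 2 * nrow(edge_set(f$gamma)), numeric(1))
  expect_equal(bic_sel$criterion + vapply(kappa, ebic_penalty, numeric(1),
                                          n = 120, p = 8, gamma = 0.5) -
                 vapply(kappa, ebic_penalty, numeric(1), n = 120, p = 8, gamma = 0),
               ebic_sel$criterion)
  edges_bic <- nrow(edge_set(bic_sel$fits[[bic_sel$index]]$gamma))
  edges_ebic <- nrow(edge_set(ebic_sel$fits[[ebic_sel$index]]$gamma))
  expect_lte(edges_ebic, edges_bic)
})

test_that("nodewise BIC follows its printed form and ignores grid order", {
  X <- center_columns(sample_mvn(toy_model(), 60, seed = 31))
  grid <- nodewise_grid(X, 2)[seq(1, 100, by = 7)]
  sel <- bic_nodewise(X, 2, grid)
  # at full shrinkage the criterion is n times the null residual sum of squares
  top <- bic_nodewise(X, 2, nodewise_grid(X, 2)[100])
  expect_equal(top$criterion, 60 * sum(X[, 2]^2), tolerance = 1e-8)
  sel_rev <- bic_nodewise(X, 2, rev(grid))
  expect_equal(sel$lambda, sel_rev$lambda)

  sgrid <- space_grid(60, 6)[c(1, 50, 100)]
  ssel <- bic_space(X, sgrid)
  ssel_rev <- bic_space(X, rev(sgrid))
  expect_equal(ssel$lambda, ssel_rev$lambda)
  null_fit <- ssel$fits[[which.max(sgrid)]]
  if (nrow(edge_set(null_fit$rho)) == 0) {
    expect_equal(ssel$criterion[which.max(sgrid)], 60 * sum(X^2), tolerance = 1e-6)
  }
})

test_that("finite-sample penalty levels match direct quantile evaluation", {
  expect_equal(fsr_lambda(100, 20, 0.05, "nr"),
               (2 / 10) * qnorm(1 - 0.05 / (2 * 400)), tolerance = 1e-10)
  expect_equal(fsr_lambda(100, 20, 0.05, "space"),
               10 * qnorm(1 - 0.05 / (2 * 400)), tolerance = 1e-10)
  alphas <- c(0.01, 0.05, 0.2, 0.5, 0.9)
  vals <- vapply(alphas, fsr_lambda, numeric(1), n = 50, p = 10, family = "nr")
  expect_true(all(diff(vals) < 0))  # strictly decreasing in alpha
  expect_error(fsr_lambda(100, 20, 1.2), "alpha")
})

test_that("cross-validation losses are reproducible under a fixed fold seed", {
  X <- center_columns(sample_mvn(toy_model(), 50, seed = 37))
  folds <- make_folds(50, 5, seed = 37)
  g <- space_grid(50, 6)[c(1, 50, 100)]
  expect_identical(cv_space(X, g, folds)$loss, cv_space(X, g, folds)$loss)
  ng <- nodewise_grid(X, 3)[c(1, 100)]
  expect_identical(cv_nodewise(X, 3, ng, folds)$loss,
                   cv_nodewise(X, 3, ng, folds)$loss)
})
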