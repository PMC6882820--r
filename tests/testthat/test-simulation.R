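test_that("chain models reproduce the banded pattern and edge counts", {
  m1 <- chain_model(20, neighbors = 1)
  expect_equal(m1$edge_count, 19)
  expect_equal(m1$gamma[1, 2], -0.4)
  expect_equal(m1$gamma[1, 3], 0)

  m2 <- chain_model(20, neighbors = 2)
  expect_equal(m2$edge_count, 37)
  expect_equal(m2$gamma[3, 5], -0.2)

  expect_equal(chain_model(60, 2)$edge_count, 117)
  expect_equal(chain_model(200, 1)$edge_count, 199)
  off <- chain_model(200, 1)$gamma
  expect_true(all(off[abs(off) > 0 & off != 1] == -0.4))

  # sigma is consistent with gamma through the precision matrix
  expect_equal(precision_to_partial(solve(m1$sigma)), m1$gamma, tolerance = 1e-8)
  expect_gt(min(eigen(m1$omega, only.values = TRUE)$values), 0)
})

test_that("nearest-neighbor models are repaired to positive definite and sized as expected", {
  m <- nearest_neighbor_model(30, k = 2, seed = 9)
  expect_gte(min(eigen(m$omega, only.values = TRUE)$values), 0.1 - 1e-12)
  expect_identical(m$gamma, precision_to_partial(m$omega))
  # deterministic under seed
  expect_identical(m$omega, nearest_neighbor_model(30, k = 2, seed = 9)$omega)

  # every node keeps at least k neighbors under the liberal rule
  m_or <- nearest_neighbor_model(25, k = 2, seed = 11, rule = "or")
  deg <- tabulate(as.vector(unclass(m_or$edges)), nbins = 25)
  expect_true(all(deg >= 2))

  # the default mutual rule reproduces the benchmark scale (~48 edges at p=60)
  counts <- vapply(1:100, function(s) {
    nearest_neighbor_model(60, k = 2, seed = s)$edge_count
  }, numeric(1))
  expect_lt(abs(mean(counts) - 48) / 48, 0.15)
})

test_that("random models match their binomial edge expectation and repair bound", {
  counts <- vapply(1:200, function(s) random_model(20, 0.1, seed = s)$edge_count,
                   numeric(1))
  expect_equal(mean(counts), 0.1 * choose(20, 2), tolerance = 0.1)

  m <- random_model(15, 0.05, seed = 13)
  expect_gte(min(eigen(m$omega, only.values = TRUE)$values), 0.1 - 1e-12)
  # vanishing edge probability leaves an identity partial correlation matrix
  m0 <- random_model(10, 1e-9, seed = 13)
  expect_equal(m0$gamma, diag(10))
})

test_that("the toy model matches its printed covariance and support", {
  m <- toy_model()
  expect_equal(diag(m$sigma), c(1.63, 1.00, 1.68, 1.00, 1.63, 1.68))
  expect_equal(m$gamma[1, 3], -0.45, tolerance = 0.02)
  expect_equal(m$edge_count, 5)
  expect_same_edges(m$edges,
                    pcsnet:::new_edge_set(rbind(c(1, 3), c(1, 6), c(3, 5),
                                                c(3, 6), c(5, 6)), 6))
})

test_that("sampling is seed-reproducible and converges to the model covariance", {
  m <- toy_model()
  X1 <- sample_mvn(m, 50, seed = 99)
  expect_identical(X1, sample_mvn(m, 50, seed = 99))
  expect_false(identical(X1, sample_mvn(m, 50, seed = 100)))

  Xbig <- sample_mvn(m, 1e5, seed = 5)
  S <- crossprod(scale(Xbig, scale = FALSE)) / nrow(Xbig)
  expect_lt(max(abs(S - m$sigma)), 0.05)
})

test_that("the sample -> unpenalized partial correlation round trip recovers the population", {
  m <- chain_model(10, neighbors = 1)
  X <- sample_mvn(m, 1e5, seed = 7)
  gamma_hat <- precision_to_partial(solve(cov(X)))
  expect_lt(max(abs(gamma_hat - m$gamma)), 0.02)
})

test_that("the experiment driver records replicates and aggregates consistently", {
  m <- toy_model()
  variants <- data.frame(method = c("space", "ridge"), tuning = c("bic", "cv"))
  exp <- run_experiment(m, ns = 50, variants = variants, reps = 3, seed = 1,
                        with_pcs = TRUE, folds = 5)
  expect_equal(nrow(exp$results), 3 * 2 * 2)  # reps x variants x stages
  expect_equal(exp$failures, 0)
  # aggregates recompute from the per-replicate records
  cell <- subset(exp$results, method == "space" & stage == "no_pcs")
  agg <- subset(exp$summary, method == "space" & stage == "no_pcs")
  expect_equal(agg$tpr, mean(cell$tpr))
  expect_equal(agg$fpr_se, sd(cell$fpr) / sqrt(3))
  # ridge without screening is dense by construction
  expect_true(all(subset(exp$results, method == "ridge" & stage == "no_pcs")$fpr == 1))
  # identical seed reproduces identical results
  exp2 <- run_experiment(m, ns = 50, variants = variants, reps = 3, seed = 1,
                         with_pcs = TRUE, folds = 5)
  expect_identical(exp$results, exp2$results)
})
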