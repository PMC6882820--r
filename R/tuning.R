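#' Deterministic K-fold assignment
#'
#' Splits `n` samples into `K` folds by a seeded random permutation; fold
#' sizes differ by at most one.  The caller's RNG state is left untouched.
#'
#' @param n Sample count.
#' @param K Number of folds (default 10).
#' @param seed Integer seed making the assignment reproducible.
#' @return Integer vector of length `n` with labels in `1..K`, attributes
#'   `K` and `seed`.
#' @export
make_folds <- function(n, K = 10, seed = 1) {
  if (K < 2 || K > n) stop("need 2 <= K <= n", call. = FALSE)
  labels <- with_seed(seed, sample(rep_len(seq_len(K), n)))
  structure(labels, K = as.integer(K), seed = as.integer(seed))
}

new_cv_curve <- function(grid, fold_losses) {
  structure(list(lambda = grid,
                 loss = colSums(fold_losses),
                 fold_losses = fold_losses,
                 K = nrow(fold_losses)),
            class = "cv_curve")
}

#' @exportS3Method base::print
print.cv_curve <- function(x, ...) {
  cat(sprintf("cv curve: %d-fold, %d grid values, loss range [%.4g, %.4g]\n",
              x$K, length(x$lambda), min(x$loss), max(x$loss)))
  invisible(x)
}

# argmin with most-regularized (largest lambda) tie-break
select_min_index <- function(crit, grid, tol = 1e-12) {
  best <- min(crit)
  ties <- which(crit <= best + tol * max(1, abs(best)))
  ties[which.max(grid[ties])]
}

#' Select a penalty from a cross-validation curve
#'
#' `rule = "min"` returns the grid value minimizing the summed fold loss
#' (ties broken toward the most regularized value).  `rule = "one_se"`
#' applies the one-standard-error rule: with
#' \eqn{\mathrm{sd}(\lambda) = \mathrm{sd}(\mathrm{CV}_1(\lambda), \ldots, \mathrm{CV}_K(\lambda))}
#' and \eqn{\mathrm{se}(\lambda) = \mathrm{sd}(\lambda)/\sqrt{K}}, it returns
#' the largest \eqn{\lambda} whose loss is within one standard error of the
#' minimum, i.e. satisfying
#' \eqn{\mathrm{CV}(\lambda) \le \mathrm{CV}(\hat\lambda) + \mathrm{se}(\hat\lambda)}.
#'
#' @param curve A `cv_curve` object.
#' @param rule `"min"` or `"one_se"`.
#' @return List with `lambda`, `index` and `rule`.
#' @export
cv_select <- function(curve, rule = c("min", "one_se")) {
  rule <- match.arg(rule)
  loss <- curve$loss
  if (anyNA(loss)) {
    stop("cross-validation losses contain NA/NaN", call. = FALSE)
  }
  idx_min <- select_min_index(loss, curve$lambda)
  if (rule == "min") {
    return(list(lambda = curve$lambda[idx_min], index = idx_min, rule = rule))
  }
  se_hat <- stats::sd(curve$fold_losses[, idx_min]) / sqrt(curve$K)
  ok <- which(loss <= loss[idx_min] + se_hat)
  idx <- ok[which.max(curve$lambda[ok])]
  list(lambda = curve$lambda[idx], index = idx, rule = rule,
       se = se_hat, index_min = idx_min)
}

#' Finite-sample penalty level for neighborhood selection and SPACE
#'
#' Closed-form penalty levels guaranteeing (under regularity conditions) at
#' most \eqn{\alpha} expected false positive edges per neighborhood:
#' \deqn{\lambda_2(\alpha) = \frac{2}{\sqrt n}\Phi^{-1}\!\left(1 - \frac{\alpha}{2p^2}\right)
#'   \quad\text{(nodewise lasso)}, \qquad
#'   \lambda_3(\alpha) = \sqrt n\,\Phi^{-1}\!\left(1 - \frac{\alpha}{2p^2}\right)
#'   \quad\text{(SPACE)}.}
#'
#' @param n Sample count.
#' @param p Variable count.
#' The nodewise-lasso level is expressed on the conventional 1/n-scaled
#' regression objective; [estimate_network()] rescales it by n/2 when
#' applying it to the unscaled objective it solves.  The SPACE level applies
#' directly to the joint objective.
#'
#' @param alpha Bound on the expected proportion of false positives, in (0, 1).
#' @param family `"nr"` (nodewise lasso) or `"space"`.
#' @return Positive penalty value.
#' @export
fsr_lambda <- function(n, p, alpha = 0.05, family = c("nr", "space")) {
  family <- match.arg(family)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  q <- stats::qnorm(1 - alpha / (2 * p^2))
  switch(family, nr = 2 / sqrt(n) * q, space = sqrt(n) * q)
}
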