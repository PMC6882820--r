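METHODS <- c("glasso", "space", "nr_and", "nr_or", "ridge")
TUNINGS <- c("cv", "cv_1se", "cv2", "cv2_1se", "bic", "ebic", "fsr")

# tuning rules meaningful for each estimator (the cv2 losses exist only for
# the graphical lasso; ebic only for the graphical lasso; fsr only for the
# l1 nodewise and SPACE estimators; ridge is tuned by cv only)
valid_tunings <- function(method) {
  switch(method,
         glasso = c("cv", "cv_1se", "cv2", "cv2_1se", "bic", "ebic"),
         space = c("cv", "cv_1se", "bic", "fsr"),
         nr_and = c("cv", "cv_1se", "bic", "fsr"),
         nr_or = c("cv", "cv_1se", "bic", "fsr"),
         ridge = c("cv", "cv_1se"))
}

# Refit a first-stage network at a fixed, already-selected penalty.
# `lambda` is a scalar (glasso, space) or per-node vector (nr, ridge).
fit_at_lambda <- function(X, method, lambda, edge_tol = 1e-8) {
  switch(method,
         glasso = {
           S <- crossprod(X) / nrow(X)
           f <- fit_glasso(S, lambda)
           list(gamma = f$gamma, edges = edge_set(f$gamma, edge_tol), fit = f)
         },
         space = {
           f <- fit_space(X, lambda)
           list(gamma = f$gamma, edges = edge_set(f$rho, edge_tol), fit = f)
         },
         nr_and = ,
         nr_or = {
           f <- fit_nodewise_lasso(X, lambda,
                                   rule = if (method == "nr_and") "and" else "or",
                                   edge_tol = edge_tol)
           list(gamma = f$gamma, edges = f$edges, fit = f)
         },
         ridge = {
           f <- fit_ridge_nodewise(X, lambda, edge_tol = edge_tol)
           list(gamma = f$gamma, edges = f$edges, fit = f)
         },
         stop("unknown method: ", method, call. = FALSE))
}

#' Estimate a sparse partial correlation network with tuned regularization
#'
#' Front-end combining a base estimator with a penalty-selection rule.
#' Methods: `"glasso"` (graphical lasso), `"space"` (joint sparse
#' regression), `"nr_and"` / `"nr_or"` (nodewise lasso with the AND/OR edge
#' rule), `"ridge"` (nodewise ridge).  Tunings: `"cv"` and `"cv_1se"`
#' (10-fold cross-validation, minimum or one-standard-error rule; for the
#' graphical lasso this is the log-likelihood loss CV1, for the others the
#' nodewise prediction error), `"cv2"` / `"cv2_1se"` (graphical lasso only:
#' nodewise prediction-error loss), `"bic"`, `"ebic"` (graphical lasso only,
#' weight `gamma`), and `"fsr"` (closed-form finite-sample penalty at level
#' `alpha`; nodewise lasso and SPACE only).
#'
#' @param X Data matrix (rows = samples); centered internally.
#' @param method One of `"glasso"`, `"space"`, `"nr_and"`, `"nr_or"`,
#'   `"ridge"`.
#' @param tuning One of `"cv"`, `"cv_1se"`, `"cv2"`, `"cv2_1se"`, `"bic"`,
#'   `"ebic"`, `"fsr"`.
#' @param folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @param gamma Extended-BIC weight in `[0, 1]` (tuning `"ebic"`).
#' @param alpha False-positive bound in (0, 1) (tuning `"fsr"`).
#' @param edge_tol Zero-detection tolerance defining the edge set.
#' @param standardize Scale columns to unit variance before estimation
#'   (columns are always mean-centered).
#' @return Object of class `ggm_network`: `gamma` (estimated partial
#'   correlation matrix), `edges` (an `edge_set`), `lambda` (selected
#'   penalty, per node where tuning is nodewise), `method`, `tuning`, `cv`
#'   (curve(s) where applicable), `folds` (the fold assignment) and `X`
#'   (the centered data, for downstream screening).
#' @examples
#' X <- sample_mvn(chain_model(10, neighbors = 1), n = 200, seed = 7)
#' net <- estimate_network(X, "space", "bic")
#' net$edges
#' @export
estimate_network <- function(X, method = METHODS, tuning = "cv",
                             folds = 10, seed = 1, gamma = 0.5, alpha = 0.05,
                             edge_tol = 1e-8, standardize = FALSE) {
  method <- match.arg(method)
  tuning <- match.arg(tuning, TUNINGS)
  if (!tuning %in% valid_tunings(method)) {
    stop(sprintf("tuning '%s' is not defined for method '%s'", tuning, method),
         call. = FALSE)
  }
  X <- center_columns(X, standardize = standardize)
  n <- nrow(X)
  p <- ncol(X)
  fold_id <- make_folds(n, folds, seed)
  cv_out <- NULL

  if (method == "glasso") {
    S <- crossprod(X) / n
    grid <- glasso_grid(S, p)
    if (tuning %in% c("cv", "cv_1se", "cv2", "cv2_1se")) {
      loss <- if (tuning %in% c("cv", "cv_1se")) "loglik" else "predict"
      rule <- if (tuning %in% c("cv", "cv2")) "min" else "one_se"
      cv_out <- cv_glasso(X, grid, fold_id, loss = loss)
      lambda <- cv_select(cv_out, rule)$lambda
    } else {
      g <- if (tuning == "bic") 0 else gamma
      lambda <- ebic_glasso(X, grid, gamma = g, edge_tol = edge_tol)$lambda
    }
  } else if (method == "space") {
    grid <- space_grid(n, p)
    if (tuning %in% c("cv", "cv_1se")) {
      cv_out <- cv_space(X, grid, fold_id)
      lambda <- cv_select(cv_out, if (tuning == "cv") "min" else "one_se")$lambda
    } else if (tuning == "bic") {
      lambda <- bic_space(X, grid, edge_tol = edge_tol)$lambda
    } else {
      lambda <- fsr_lambda(n, p, alpha, "space")
    }
  } else {  # nodewise lasso / ridge: per-node tuning
    penalty <- if (method == "ridge") "ridge" else "lasso"
    if (tuning == "fsr") {
      # the closed-form level is stated for the 1/n-scaled regression
      # objective; rescale by n/2 for the unscaled objective solved here
      lambda <- rep(n / 2 * fsr_lambda(n, p, alpha, "nr"), p)
    } else {
      lambda <- numeric(p)
      cv_out <- vector("list", p)
      for (i in seq_len(p)) {
        grid_i <- nodewise_grid(X, i)
        if (tuning %in% c("cv", "cv_1se")) {
          curve <- cv_nodewise(X, i, grid_i, fold_id, penalty = penalty)
          cv_out[[i]] <- curve
          lambda[i] <- cv_select(curve,
                                 if (tuning == "cv") "min" else "one_se")$lambda
        } else {  # bic (lasso only)
          lambda[i] <- bic_nodewise(X, i, grid_i, edge_tol = edge_tol)$lambda
        }
      }
    }
  }

  first <- fit_at_lambda(X, method, lambda, edge_tol = edge_tol)
  structure(list(gamma = first$gamma, edges = first$edges, lambda = lambda,
                 method = method, tuning = tuning, fit = first$fit,
                 cv = cv_out, folds = fold_id, edge_tol = edge_tol, X = X),
            class = "ggm_network")
}

#' @exportS3Method base::print
print.ggm_network <- function(x, ...) {
  lam <- if (length(x$lambda) > 1) {
    sprintf("per-node lambda in [%.4g, %.4g]", min(x$lambda), max(x$lambda))
  } else {
    sprintf("lambda = %.4g", x$lambda)
  }
  cat(sprintf("ggm_network: %s-%s, p = %d, %d edges, %s\n",
              x$method, x$tuning, ncol(x$gamma), nrow(x$edges), lam))
  invisible(x)
}
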