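new_ggm_model <- function(name, gamma, omega, seed = NA_integer_) {
  sigma <- solve(omega)
  sigma <- (sigma + t(sigma)) / 2
  edges <- edge_set(gamma, 1e-12)
  structure(list(name = name, p = ncol(gamma), gamma = gamma, omega = omega,
                 sigma = sigma, edges = edges, edge_count = nrow(edges),
                 seed = seed),
            class = "ggm_model")
}

#' @exportS3Method base::print
print.ggm_model <- function(x, ...) {
  cat(sprintf("ggm_model '%s': p = %d, %d edges\n", x$name, x$p, x$edge_count))
  invisible(x)
}

#' Chain-graph population model
#'
#' Banded partial correlation structure: with `neighbors = 1`, each node is
#' tied to its immediate neighbors with partial correlation -0.4 (p - 1
#' edges); with `neighbors = 2`, a second band at -0.2 is added (further
#' p - 2 edges).  The precision matrix is built with unit diagonal and
#' \eqn{\omega_{ij} = -\rho_{ij}} (partial correlations are invariant to the
#' diagonal scale of \eqn{\Omega}), then inverted for the sampling
#' covariance.
#'
#' @param p Number of variables (at least 3).
#' @param neighbors Band count, 1 or 2.
#' @return A `ggm_model` (fields `gamma`, `omega`, `sigma`, `edges`,
#'   `edge_count`).
#' @export
chain_model <- function(p, neighbors = 1) {
  if (p < 3) stop("need p >= 3", call. = FALSE)
  if (!neighbors %in% 1:2) stop("neighbors must be 1 or 2", call. = FALSE)
  gamma <- diag(p)
  idx <- cbind(seq_len(p - 1), seq_len(p - 1) + 1)
  gamma[idx] <- -0.4
  gamma[idx[, c(2, 1)]] <- -0.4
  if (neighbors == 2) {
    idx2 <- cbind(seq_len(p - 2), seq_len(p - 2) + 2)
    gamma[idx2] <- -0.2
    gamma[idx2[, c(2, 1)]] <- -0.2
  }
  omega <- -gamma
  diag(omega) <- 1
  if (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("chain precision matrix is not positive definite", call. = FALSE)
  }
  new_ggm_model(paste0("chain", neighbors), gamma, omega)
}

# positive-definiteness repair: Omega + (|lambda_min| + 0.1) I, applied
# unconditionally; the repaired matrix has smallest eigenvalue >= 0.1
pd_repair <- function(omega) {
  lmin <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  omega + (abs(lmin) + 0.1) * diag(nrow(omega))
}

#' Nearest-neighbor-graph population model
#'
#' Scatters p points uniformly on the unit square and connects each point to
#' its `k` nearest neighbors (Euclidean distance, ties broken by lower
#' index).  With `rule = "and"` (default) an edge requires the relation to
#' be mutual; `rule = "or"` keeps every directed nearest-neighbor relation.
#' The default reproduces the realized edge counts of the benchmark designs
#' this model emulates (about 14, 42 and 141 edges at p = 20, 60, 200 for
#' k = 2).  Edge weights of the precision matrix are drawn uniformly from
#' \eqn{[-1,-0.5] \cup [0.5,1]}, the diagonal is set to 1, the matrix is
#' made positive definite by adding \eqn{(|\lambda_{\min}| + 0.1) I}, and
#' partial correlations follow by normalizing and flipping the sign of the
#' off-diagonal (i.e. [precision_to_partial()]).
#'
#' @param p Number of variables (at least 3).
#' @param k Neighbors per node.
#' @param seed Integer seed; the model is deterministic given the seed.
#' @param rule `"and"` (mutual nearest neighbors) or `"or"`.
#' @return A `ggm_model`.
#' @export
nearest_neighbor_model <- function(p, k = 2, seed = 1, rule = c("and", "or")) {
  rule <- match.arg(rule)
  if (p < 3) stop("need p >= 3", call. = FALSE)
  with_seed(seed, {
    pts <- matrix(stats::runif(2 * p), p, 2)
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    A <- matrix(FALSE, p, p)
    for (i in seq_len(p)) A[i, order(d[i, ])[seq_len(k)]] <- TRUE
    adj <- if (rule == "and") A & t(A) else A | t(A)
    omega <- diag(p)
    up <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(up) > 0) {
      w <- stats::runif(nrow(up), 0.5, 1) * sample(c(-1, 1), nrow(up), replace = TRUE)
      omega[up] <- w
      omega[up[, c(2, 1), drop = FALSE]] <- w
    }
    omega <- pd_repair(omega)
    new_ggm_model("nearest_neighbor", precision_to_partial(omega), omega,
                  seed = seed)
  })
}

#' Random-graph population model
#'
#' Each upper-triangular entry of the precision matrix is set to 0.3 with
#' probability `prob` (and mirrored), the diagonal to 1; the matrix is made
#' positive definite by adding \eqn{(|\lambda_{\min}| + 0.1) I}; partial
#' correlations follow by normalizing and flipping the off-diagonal sign.
#' Typical edge probabilities in the benchmark designs are 0.1, 0.01 and
#' 0.001 for p = 20, 60 and 200.
#'
#' @param p Number of variables.
#' @param prob Edge probability in (0, 1).
#' @param seed Integer seed.
#' @return A `ggm_model`.
#' @export
random_model <- function(p, prob, seed = 1) {
  if (prob <= 0 || prob >= 1) stop("prob must be in (0, 1)", call. = FALSE)
  with_seed(seed, {
    omega <- diag(p)
    up <- upper.tri(omega)
    omega[up] <- 0.3 * (stats::runif(sum(up)) < prob)
    omega[lower.tri(omega)] <- t(omega)[lower.tri(omega)]
    omega <- pd_repair(omega)
    new_ggm_model("random", precision_to_partial(omega), omega, seed = seed)
  })
}

#' Six-variable toy population model
#'
#' The small worked example used throughout the package: a 6-variable
#' Gaussian with covariance
#' \deqn{\Sigma = \begin{pmatrix} 1.63 & 0 & -0.70 & 0 & 0.63 & -0.70 \\ \cdot & 1 & 0 & 0 & 0 & 0 \\ \cdot & \cdot & 1.68 & 0 & -0.70 & -0.13 \\ \cdot & \cdot & \cdot & 1 & 0 & 0 \\ \cdot & \cdot & \cdot & \cdot & 1.63 & -0.70 \\ \cdot & \cdot & \cdot & \cdot & \cdot & 1.68 \end{pmatrix}}
#' whose implied partial correlation network has exactly 5 edges, all with
#' partial correlation -0.45 (to two decimals): (1,3), (1,6), (3,5), (3,6),
#' (5,6).  Notably the pair (1,5) is marginally correlated but conditionally
#' independent.
#'
#' @return A `ggm_model` whose `sigma` is the matrix above.
#' @export
toy_model <- function() {
  sigma <- matrix(c(
     1.63, 0.00, -0.70, 0.00,  0.63, -0.70,
     0.00, 1.00,  0.00, 0.00,  0.00,  0.00,
    -0.70, 0.00,  1.68, 0.00, -0.70, -0.13,
     0.00, 0.00,  0.00, 1.00,  0.00,  0.00,
     0.63, 0.00, -0.70, 0.00,  1.63, -0.70,
    -0.70, 0.00, -0.13, 0.00, -0.70,  1.68), 6, 6, byrow = TRUE)
  omega <- solve(sigma)
  omega <- (omega + t(omega)) / 2
  gamma <- precision_to_partial(omega)
  # entries that are zero only up to the printed rounding of sigma are
  # structural zeros of the model
  gamma[abs(gamma) < 0.01] <- 0
  model <- new_ggm_model("toy", gamma, omega)
  model$sigma <- sigma
  model
}

#' Sample from a population model
#'
#' Draws n independent observations from the p-variate Gaussian distribution
#' with mean zero and covariance `model$sigma`.
#'
#' @param model A `ggm_model`.
#' @param n Sample size.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return n x p numeric matrix.
#' @export
sample_mvn <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "ggm_model"))
  with_seed(seed, MASS::mvrnorm(n, mu = rep(0, model$p), Sigma = model$sigma))
}

#' The nineteen standard method-tuning combinations
#'
#' The roster of estimator x tuning variants used by the benchmark study:
#' six graphical-lasso tunings (CV1, CV1-1se, CV2, CV2-1se, BIC, EBIC), four
#' each for SPACE, NR-AND and NR-OR (CV, CV-1se, BIC, FSR), and Ridge-CV.
#'
#' @return Data frame with columns `method`, `tuning` and `label` (19 rows).
#' @export
standard_variants <- function() {
  v <- rbind(
    expand.grid(method = "glasso",
                tuning = c("cv", "cv_1se", "cv2", "cv2_1se", "bic", "ebic"),
                stringsAsFactors = FALSE),
    expand.grid(method = c("space", "nr_and", "nr_or"),
                tuning = c("cv", "cv_1se", "bic", "fsr"),
                stringsAsFactors = FALSE),
    data.frame(method = "ridge", tuning = "cv", stringsAsFactors = FALSE))
  v$label <- paste(v$method, v$tuning, sep = "-")
  rownames(v) <- NULL
  v
}

# deterministic per-replicate seed derived from the base seed; kept within
# the 32-bit integer range
replicate_seed <- function(seed, rep, offset = 0L) {
  as.integer((as.numeric(seed) * 7919 + rep * 104729 + offset * 31) %%
               .Machine$integer.max) + 1L
}

#' Replicated network-recovery experiment
#'
#' Draws `reps` datasets from each population model at each sample size,
#' runs every requested estimator x tuning variant with and (optionally)
#' without the screening stage, and scores each fitted network against the
#' model's true edge set with [recovery_metrics()].
#'
#' @param models A `ggm_model` or list of them (the same fixed model is
#'   reused across replicates).
#' @param ns Vector of sample sizes.
#' @param variants Data frame with columns `method` and `tuning` (default
#'   [standard_variants()]).
#' @param reps Replicates per cell.
#' @param seed Base seed; replicate data and fold assignments derive from it.
#' @param with_pcs Also run the screening stage on every fitted network.
#' @param folds Cross-validation folds.
#' @param alpha,gamma Passed to the tuning rules.
#' @return Object of class `ggm_experiment`: `results` (one row per
#'   replicate x variant x stage with TP/FP/TN/FN and TPR/FPR), `summary`
#'   (cell means with standard errors), `failures` (count of fits that
#'   errored, excluded from the averages).
#' @export
run_experiment <- function(models, ns, variants = standard_variants(),
                           reps = 100, seed = 1, with_pcs = TRUE, folds = 10,
                           alpha = 0.05, gamma = 0.5) {
  if (inherits(models, "ggm_model")) models <- list(models)
  rows <- list()
  failures <- 0L
  for (m_idx in seq_along(models)) {
    model <- models[[m_idx]]
    for (n in ns) {
      for (r in seq_len(reps)) {
        data_seed <- replicate_seed(seed, r, m_idx * 1000L + n)
        X <- sample_mvn(model, n, seed = data_seed)
        for (v in seq_len(nrow(variants))) {
          method <- variants$method[v]
          tuning <- variants$tuning[v]
          res <- tryCatch({
            net <- estimate_network(X, method, tuning, folds = folds,
                                    seed = data_seed, alpha = alpha,
                                    gamma = gamma)
            out <- list(no_pcs = recovery_metrics(net$edges, model$edges))
            if (with_pcs) {
              scr <- suppressWarnings(pcs(X, network = net))
              out$pcs <- recovery_metrics(scr$edges, model$edges)
            }
            out
          }, error = function(e) {
            message(sprintf("fit failed (%s-%s, n=%d, rep=%d): %s",
                            method, tuning, n, r, conditionMessage(e)))
            NULL
          })
          if (is.null(res)) {
            failures <- failures + 1L
            next
          }
          for (stage in names(res)) {
            met <- res[[stage]]
            rows[[length(rows) + 1L]] <- data.frame(
              model = model$name, p = model$p, n = n, rep = r,
              method = method, tuning = tuning,
              stage = if (stage == "pcs") "pcs" else "no_pcs",
              tp = met$tp, fp = met$fp, tn = met$tn, fn = met$fn,
              tpr = met$tpr, fpr = met$fpr, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(tpr, fpr, tp, fp) ~ model + p + n + method + tuning + stage,
    data = results, FUN = mean)
  se <- stats::aggregate(
    cbind(tpr, fpr) ~ model + p + n + method + tuning + stage,
    data = results, FUN = function(x) stats::sd(x) / sqrt(length(x)))
  names(se)[names(se) %in% c("tpr", "fpr")] <- c("tpr_se", "fpr_se")
  summary <- merge(summary, se,
                   by = c("model", "p", "n", "method", "tuning", "stage"))
  structure(list(results = results, summary = summary, failures = failures),
            class = "ggm_experiment")
}

#' @exportS3Method base::print
print.ggm_experiment <- function(x, ...) {
  cat(sprintf("ggm_experiment: %d replicate records, %d failures\n",
              nrow(x$results), x$failures))
  print(x$summary)
  invisible(x)
}
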