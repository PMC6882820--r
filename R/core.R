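#' Convert a precision matrix to a partial correlation matrix
#'
#' Uses the standard relation between the entries of the inverse covariance
#' matrix \eqn{\Omega = [\omega_{ij}]} and the partial correlations:
#' \deqn{\rho_{ij|V \setminus \{i,j\}} = -\omega_{ij} / \sqrt{\omega_{ii}\,\omega_{jj}}.}
#'
#' @param omega Symmetric numeric matrix with strictly positive diagonal
#'   (a precision matrix).
#' @return Symmetric matrix with unit diagonal whose off-diagonal entries are
#'   the partial correlations.
#' @examples
#' sigma <- toy_model()$sigma
#' precision_to_partial(solve(sigma))
#' @export
precision_to_partial <- function(omega) {
  omega <- as.matrix(omega)
  check_square_symmetric(omega, "omega")
  d <- diag(omega)
  if (any(d <= 0)) {
    stop("invalid precision matrix: non-positive diagonal entry", call. = FALSE)
  }
  s <- 1 / sqrt(d)
  gamma <- -omega * tcrossprod(s)
  diag(gamma) <- 1
  gamma <- (gamma + t(gamma)) / 2
  dimnames(gamma) <- dimnames(omega)
  gamma
}

#' Convert nodewise regression weights to partial correlations
#'
#' Each pair of regression weights \eqn{\beta_{ij}} (weight of \eqn{X_j} in
#' the regression of \eqn{X_i}) and \eqn{\beta_{ji}} determines the partial
#' correlation through
#' \eqn{\rho_{ij} = \mathrm{sign}(\beta_{ij}) \sqrt{\beta_{ij}\beta_{ji}}},
#' valid when the two weights agree in sign.  Finite-sample fits can produce
#' discordant signs, for which the geometric mean is undefined; those entries
#' are set to zero (consistent with the sparsity goal).
#'
#' @param beta p x p matrix of regression weights with zero diagonal;
#'   `beta[i, j]` is the weight of variable j in the regression of variable i.
#' @param resid_var Optional length-p vector of positive residual variances;
#'   only validated, the symmetric geometric-mean form does not use it.
#' @return Symmetric partial correlation matrix with unit diagonal.
#' @export
regression_to_partial <- function(beta, resid_var = NULL) {
  beta <- as.matrix(beta)
  if (nrow(beta) != ncol(beta)) stop("beta must be square", call. = FALSE)
  if (!is.null(resid_var) && any(resid_var < 0)) {
    stop("invalid input: negative residual variance", call. = FALSE)
  }
  prod <- beta * t(beta)
  gamma <- sign(beta) * sqrt(pmax(prod, 0))
  gamma[prod < 0] <- 0  # discordant signs: geometric mean undefined, drop edge
  # symmetric by construction (prod > 0 implies matching signs); enforce exactly
  gamma[lower.tri(gamma)] <- t(gamma)[lower.tri(gamma)]
  diag(gamma) <- 1
  dimnames(gamma) <- dimnames(beta)
  gamma
}

#' Edge set of a partial correlation matrix
#'
#' Returns the unordered variable pairs whose partial correlation exceeds a
#' small tolerance in absolute value.  The default tolerance 1e-8 is a
#' solver-noise floor: the l1-penalized estimators return exact zeros, so any
#' larger entry is a structural edge.
#'
#' @param gamma Symmetric matrix (typically a partial correlation matrix).
#' @param tol Non-negative threshold; entries with `abs(value) > tol` count
#'   as edges.
#' @return An object of class `edge_set`: a two-column integer matrix of pairs
#'   (i < j) with attribute `p`, the node count.
#' @export
edge_set <- function(gamma, tol = 1e-8) {
  gamma <- as.matrix(gamma)
  p <- nrow(gamma)
  keep <- which(abs(gamma) > tol & upper.tri(gamma), arr.ind = TRUE)
  new_edge_set(keep[order(keep[, 1], keep[, 2]), , drop = FALSE], p)
}

new_edge_set <- function(pairs, p) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  colnames(pairs) <- c("i", "j")
  stopifnot(all(pairs[, 1] < pairs[, 2]), all(pairs >= 1), all(pairs <= p))
  structure(pairs, p = as.integer(p), class = "edge_set")
}

#' @exportS3Method base::print
print.edge_set <- function(x, ...) {
  cat("edge set:", nrow(x), "edges on", attr(x, "p"), "nodes\n")
  if (nrow(x) > 0) {
    print(utils::head(cbind(i = x[, 1], j = x[, 2]), 20))
    if (nrow(x) > 20) cat("...\n")
  }
  invisible(x)
}

edge_key <- function(edges) {
  if (nrow(edges) == 0) character(0) else paste(edges[, 1], edges[, 2])
}

#' Edge-recovery metrics against a reference network
#'
#' Counts true/false positives and negatives over all p(p-1)/2 unordered
#' pairs and computes
#' \deqn{\mathrm{TPR} = \mathrm{TP}/(\mathrm{TP}+\mathrm{FN}), \quad
#'       \mathrm{FPR} = \mathrm{FP}/(\mathrm{TN}+\mathrm{FP}),}
#' reported as `NaN` when a denominator is zero.
#'
#' @param estimated,truth `edge_set` objects on the same node count.
#' @return List with integer counts `tp`, `fp`, `tn`, `fn` and rates `tpr`,
#'   `fpr`.
#' @export
recovery_metrics <- function(estimated, truth) {
  p <- attr(estimated, "p")
  if (!identical(p, attr(truth, "p"))) {
    stop("edge sets have different node counts", call. = FALSE)
  }
  total <- p * (p - 1) / 2
  ek <- edge_key(estimated)
  tk <- edge_key(truth)
  tp <- sum(ek %in% tk)
  fp <- length(ek) - tp
  fn <- length(tk) - tp
  tn <- total - tp - fp - fn
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NaN,
       fpr = if (tn + fp > 0) fp / (tn + fp) else NaN)
}

#' Center a data matrix by column
#'
#' All estimators in the package work on mean-centered columns (the penalized
#' objectives carry no intercepts).  Columns are not scaled to unit variance
#' unless `standardize = TRUE`.
#'
#' @param x Numeric matrix (rows = samples, columns = variables).
#' @param standardize Also divide each column by its standard deviation.
#' @return Centered matrix with attribute `centered = TRUE`.
#' @export
center_columns <- function(x, standardize = FALSE) {
  x <- validate_data(x)
  x <- scale(x, center = TRUE, scale = standardize)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  attr(x, "centered") <- TRUE
  x
}

validate_data <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("data matrix must be numeric", call. = FALSE)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("data matrix needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (anyNA(x)) stop("data matrix contains missing values", call. = FALSE)
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop("constant column in data matrix", call. = FALSE)
  }
  x
}

check_square_symmetric <- function(m, name, tol = 1e-10) {
  if (nrow(m) != ncol(m)) stop(name, " must be square", call. = FALSE)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    stop(name, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}

# run expr with a private RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
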