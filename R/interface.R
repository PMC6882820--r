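#' Combine networks estimated by several method variants
#'
#' Keeps the edges supported by at least `min_support` of the supplied
#' networks.  With `min_support = 1` this is the union, with
#' `min_support = length(networks)` the intersection.  The default of 2
#' matches the practice of retaining edges found by at least two screened
#' networks when many estimator variants are run on the same data.
#'
#' @param networks List of `edge_set` objects on the same node count.
#' @param min_support Minimum number of networks an edge must appear in.
#' @return An `edge_set`.
#' @export
combine_networks <- function(networks, min_support = 2) {
  stopifnot(length(networks) >= 1)
  p <- attr(networks[[1]], "p")
  if (!all(vapply(networks, function(e) identical(attr(e, "p"), p), logical(1)))) {
    stop("networks have different node counts", call. = FALSE)
  }
  keys <- unlist(lapply(networks, edge_key))
  support <- table(keys)
  keep <- names(support)[support >= min_support]
  if (length(keep) == 0) return(new_edge_set(matrix(integer(0), 0, 2), p))
  pairs <- do.call(rbind, lapply(strsplit(keep, " "), as.integer))
  new_edge_set(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE], p)
}

#' Nonparanormal (Gaussian copula) transform
#'
#' Replaces each column by truncated-Winsorized normal scores: the empirical
#' CDF (midranks, so ties map to identical scores) is clipped to
#' \eqn{[\delta_n, 1-\delta_n]} with the truncation level
#' \eqn{\delta_n = 1 / (4 n^{1/4} \sqrt{\pi \log n})}, mapped through the
#' standard normal quantile function, and rescaled to unit variance.  The
#' result is invariant to strictly increasing marginal transformations of
#' the input, making non-Gaussian (e.g. skewed or ordinal) data amenable to
#' Gaussian graphical modeling.
#'
#' @param X Numeric data matrix without constant columns.
#' @return Matrix of the same dimensions with transformed columns.
#' @export
nonparanormal <- function(X) {
  X <- validate_data(X)
  n <- nrow(X)
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  apply(X, 2, function(x) {
    u <- rank(x, ties.method = "average") / n
    z <- stats::qnorm(pmin(pmax(u, delta), 1 - delta))
    z / stats::sd(z)
  })
}

#' Read a numeric matrix from CSV/TSV
#'
#' Expects a header row of variable names; a square matrix written by
#' [write_matrix()] round-trips with its row and column labels.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma) unless `sep` is given.
#' @param sep Optional field separator.
#' @param rownames Whether the first column holds row labels.
#' @return Numeric matrix.
#' @export
read_matrix <- function(path, sep = NULL, rownames = FALSE) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (rownames) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric columns in ", path, call. = FALSE)
  if (anyNA(m)) stop("missing values in ", path, call. = FALSE)
  if (rownames) rownames(m) <- rn
  m
}

#' Write a numeric matrix to CSV/TSV
#'
#' @param m Numeric matrix.
#' @param path Destination; delimiter inferred from the extension as in
#'   [read_matrix()].
#' @param rownames Also write row labels as a first column.
#' @export
write_matrix <- function(m, path, rownames = FALSE) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  # full 17-significant-digit formatting so numeric round trips are lossless
  df <- as.data.frame(apply(m, 2, sprintf, fmt = "%.17g"))
  names(df) <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  if (rownames) df <- cbind(row = rownames(m) %||% seq_len(nrow(m)), df)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an edge list as TSV
#'
#' Three columns: `node_i`, `node_j`, `partial_correlation` (taken from
#' `gamma` when supplied, otherwise `NA`).
#'
#' @param edges An `edge_set`.
#' @param path Destination file.
#' @param gamma Optional partial correlation matrix to annotate the edges.
#' @export
write_edges <- function(edges, path, gamma = NULL) {
  df <- data.frame(node_i = edges[, 1], node_j = edges[, 2],
                   partial_correlation = if (is.null(gamma)) NA_real_
                                         else gamma[edges])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' Serializes the configuration and results of a screening run (selected
#' penalty and threshold, grids, cross-validation losses, seeds) so the run
#' can be reproduced from the report alone.
#'
#' @param fit A `pcs_network` or `ggm_network`.
#' @param path Destination `.json` file.
#' @export
write_report <- function(fit, path) {
  if (inherits(fit, "pcs_network")) {
    fs <- fit$first_stage
    report <- list(
      type = "pcs_network",
      method = fs$method, tuning = fs$tuning,
      lambda = fs$lambda, tau = fit$tau,
      folds = list(K = attr(fs$folds, "K"), seed = attr(fs$folds, "seed")),
      first_stage_edges = nrow(fs$edges), screened_edges = nrow(fit$edges),
      edges = list(node_i = fit$edges[, 1], node_j = fit$edges[, 2]),
      tau_curve = if (is.null(fit$tau_curve)) NULL else
        list(tau = fit$tau_curve$lambda, loss = fit$tau_curve$loss),
      package_version = as.character(utils::packageVersion("pcsnet")))
  } else {
    stopifnot(inherits(fit, "ggm_network"))
    report <- list(
      type = "ggm_network",
      method = fit$method, tuning = fit$tuning, lambda = fit$lambda,
      folds = list(K = attr(fit$folds, "K"), seed = attr(fit$folds, "seed")),
      edges = list(node_i = fit$edges[, 1], node_j = fit$edges[, 2]),
      package_version = as.character(utils::packageVersion("pcsnet")))
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
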