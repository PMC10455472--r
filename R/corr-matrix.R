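#' Labeled correlation matrix with sample size
#'
#' The basic input of every network analysis in this package: a symmetric
#' correlation matrix, the item labels, and the number of observations the
#' matrix summarizes (needed by the EBIC and by the parametric bootstrap).
#'
#' @param values numeric p x p correlation matrix (symmetric, unit diagonal).
#' @param n sample size the matrix summarizes.
#' @param labels character vector of item names; defaults to the matrix
#'   dimnames, then to `V1..Vp`.
#' @return An object of class `corr_matrix`: a list with elements `values`
#'   (labeled matrix), `labels` and `n`.
#' @examples
#' m <- diag(3)
#' m[1, 2] <- m[2, 1] <- 0.4
#' corr_matrix(m, n = 100, labels = c("A", "B", "C"))
#' @export
corr_matrix <- function(values, n, labels = NULL) {
  values <- as.matrix(values)
  p <- nrow(values)
  if (ncol(values) != p) stop("correlation matrix must be square")
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("V", seq_len(p))
  }
  if (length(labels) != p) stop("need one label per variable")
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (max(abs(values - t(values))) > 1e-12)
    stop("correlation matrix is not symmetric (max asymmetry ",
         format(max(abs(values - t(values)))), ")")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values) - 1)) > 1e-8)
    stop("correlation matrix must have a unit diagonal")
  diag(values) <- 1
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("n must be a single sample size >= 2")
  if (n <= p)
    warning("sample size n = ", n, " does not exceed the number of variables p = ",
            p, "; estimates will be unstable")
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, n = as.integer(n)),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("Correlation matrix:", length(x$labels), "variables, n =", x$n, "\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Number of variables in a correlation matrix
#' @param x a `corr_matrix`.
#' @return integer count of variables.
#' @export
n_items <- function(x) length(x$labels)

#' Repair a correlation matrix that is not positive semi-definite
#'
#' Resampled or hand-entered matrices can have (slightly) negative
#' eigenvalues. Eigenvalues below the floor are clipped and the matrix is
#' re-standardized to a unit diagonal. Used automatically inside the
#' bootstrap so that degenerate replicates do not abort a run.
#'
#' @param values numeric symmetric matrix.
#' @param floor eigenvalue floor (default `1e-6`).
#' @param warn emit a warning when a repair was necessary?
#' @return repaired matrix with unit diagonal.
#' @export
repair_correlation <- function(values, floor = 1e-6, warn = TRUE) {
  e <- eigen(values, symmetric = TRUE)
  if (min(e$values) >= floor) return(values)
  if (warn)
    warning("matrix is not positive definite (min eigenvalue ",
            format(min(e$values), digits = 3), "); clipping at ", floor)
  v <- pmax(e$values, floor)
  m <- e$vectors %*% (v * t(e$vectors))
  m <- stats::cov2cor(m)
  dimnames(m) <- dimnames(values)
  (m + t(m)) / 2
}

#' Compute a labeled correlation matrix from raw scores
#'
#' Pearson correlations on complete data (missing values are an error: the
#' parametric bootstrap and the likelihood both assume complete rows).
#'
#' @param scores numeric n x p matrix or data frame of raw scores.
#' @param labels optional item names (default: column names).
#' @return a [corr_matrix()].
#' @export
corr_from_scores <- function(scores, labels = NULL) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("scores contain missing values; complete data required")
  if (!is.null(labels)) colnames(scores) <- labels
  corr_matrix(stats::cor(scores), n = nrow(scores))
}

#' Read / write labeled correlation matrices as CSV
#'
#' The on-disk format is a CSV with a header row of item labels and a leading
#' label column; values round-trip at 15 significant digits.
#'
#' @param path file path.
#' @param n sample size to attach on read (the CSV stores only the matrix).
#' @return `read_corr_csv()` returns a [corr_matrix()]; `write_corr_csv()`
#'   returns `path` invisibly.
#' @export
read_corr_csv <- function(path, n) {
  d <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- labels
  corr_matrix(m, n = n, labels = labels)
}

#' @param corr a `corr_matrix` to write.
#' @rdname read_corr_csv
#' @export
write_corr_csv <- function(corr, path) {
  m <- signif(corr$values, 15)
  d <- data.frame(item = corr$labels, m, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
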