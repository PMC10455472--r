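#' Settings for regularized network estimation
#'
#' @param gamma EBIC hyperparameter; larger values prefer sparser networks.
#'   The conventional starting value for dimensionality analysis is 0.50.
#' @param n_lambda number of penalty values on the log-spaced path
#'   (default 100).
#' @param lambda_min_ratio ratio of the smallest to the largest penalty
#'   (default 0.01). The largest penalty is the maximum absolute off-diagonal
#'   correlation, at which the network is empty.
#' @return an `estimation_settings` object.
#' @export
estimation_settings <- function(gamma = 0.50, n_lambda = 100L,
                                lambda_min_ratio = 0.01) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (n_lambda < 2) stop("n_lambda must be >= 2")
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1)
    stop("lambda_min_ratio must be in (0, 1)")
  structure(list(gamma = gamma, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio),
            class = "estimation_settings")
}

#' Partial correlations from the precision matrix
#'
#' Inverts the correlation matrix and standardizes the negated off-diagonal
#' of the precision matrix:
#' `rho_ij = -theta_ij / sqrt(theta_ii * theta_jj)`. The diagonal is set to
#' zero by convention. A non-positive-definite input is repaired by
#' eigenvalue clipping first; if it is still effectively singular the
#' function errors, naming the smallest eigenvalue.
#'
#' @param corr a [corr_matrix()] (or plain matrix) with at least 3 variables.
#' @param repair repair near-singular input by eigenvalue clipping?
#' @return p x p matrix of partial correlations, zero diagonal.
#' @examples
#' m <- matrix(0.5, 3, 3); diag(m) <- 1
#' partial_correlations(corr_matrix(m, n = 100))  # all entries 1/3
#' @export
partial_correlations <- function(corr, repair = TRUE) {
  values <- if (inherits(corr, "corr_matrix")) corr$values else as.matrix(corr)
  if (nrow(values) < 3)
    stop("network estimation needs at least 3 variables")
  if (repair) values <- repair_correlation(values, warn = FALSE)
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("correlation matrix is singular (smallest eigenvalue ",
         format(min(ev), digits = 3), "); cannot invert")
  theta <- solve(values)
  pc <- -theta / sqrt(diag(theta) %o% diag(theta))
  diag(pc) <- 0
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- dimnames(values)
  pc
}

# Internal constructor for the network object.
new_ggm_network <- function(weights, labels, lambda, gamma, ebic,
                            precision = NULL) {
  diag(weights) <- 0
  weights <- (weights + t(weights)) / 2
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights,
                 lambda = lambda, gamma = gamma, ebic = ebic,
                 edge_count = sum(abs(weights[upper.tri(weights)]) > 1e-8),
                 precision = precision),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat("Gaussian graphical model:", length(x$labels), "nodes,",
      x$edge_count, "edges\n")
  if (!is.na(x$lambda))
    cat(sprintf("  lambda = %.4g, gamma = %.2f, EBIC = %.2f\n",
                x$lambda, x$gamma, x$ebic))
  invisible(x)
}

#' Fit a graphical lasso model at a single penalty
#'
#' Solves the L1-penalized Gaussian likelihood for the precision matrix
#' (block coordinate descent; diagonal unpenalized) and converts the result
#' to a partial-correlation network. At `lambda = 0` this reproduces the
#' unregularized precision-based partial correlations; at
#' `lambda >= max |r_ij|` the network is empty.
#'
#' @param corr a [corr_matrix()] with known `n`.
#' @param lambda penalty (>= 0).
#' @param gamma EBIC hyperparameter recorded (and used to score) the model.
#' @param tol convergence tolerance on the average absolute change of the
#'   working covariance (relative to the mean absolute off-diagonal input).
#' @param max_iter maximum sweeps.
#' @return a `ggm_network`.
#' @export
glasso_fit <- function(corr, lambda, gamma = 0.50, tol = 1e-7,
                       max_iter = 500L) {
  if (lambda < 0) stop("lambda must be >= 0")
  fits <- glasso_path(corr, lambda, tol = tol, max_iter = max_iter)
  net <- fits$networks[[1]]
  if (!fits$converged[1])
    stop("graphical lasso did not converge at lambda = ", format(lambda),
         " within ", max_iter, " iterations")
  net$gamma <- gamma
  net$ebic <- ebic_score(net, corr, gamma = gamma)
  net
}

# Fit the whole penalty path in one compiled call (warm starts).
# Returns networks (list of ggm_network, ebic left NA), iterations, converged.
glasso_path <- function(corr, lambdas, tol = 1e-7, max_iter = 500L) {
  values <- repair_correlation(corr$values, warn = FALSE)
  res <- glasso_path_cpp(values, as.numeric(lambdas), tol,
                         as.integer(max_iter))
  networks <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    theta <- res$theta[[i]]
    d <- sqrt(diag(theta))
    pc <- -theta / (d %o% d)
    diag(pc) <- 0
    networks[[i]] <- new_ggm_network(pc, corr$labels, lambda = lambdas[i],
                                     gamma = NA_real_, ebic = NA_real_,
                                     precision = theta)
  }
  list(networks = networks, iterations = res$iterations,
       converged = res$converged)
}

#' Extended Bayesian information criterion of a fitted network
#'
#' `EBIC = -2 l + E log(n) + 4 gamma E log(p)` where `E` is the number of
#' nonzero upper-triangle partial correlations and the Gaussian
#' log-likelihood is `l = (n/2) (log det Theta - tr(S Theta))`, dropping the
#' `-(n/2) p log(2 pi)` constant shared by all candidate models. Lower is
#' better.
#'
#' @param network a `ggm_network` holding the precision estimate.
#' @param corr the [corr_matrix()] the network was estimated from (supplies
#'   the sample matrix `S` and `n`).
#' @param gamma EBIC hyperparameter (default: the network's own).
#' @return the EBIC value.
#' @export
ebic_score <- function(network, corr, gamma = network$gamma) {
  theta <- network$precision
  if (is.null(theta)) stop("network carries no precision estimate")
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("precision estimate is not positive definite")
  s <- corr$values
  n <- corr$n
  p <- nrow(s)
  loglik <- (n / 2) * (sum(log(ev)) - sum(s * theta))
  e <- network$edge_count
  -2 * loglik + e * log(n) + 4 * gamma * e * log(p)
}

#' Estimate the EBIC-selected regularized partial-correlation network
#'
#' Builds a log-spaced penalty path from `lambda_max` (the largest absolute
#' off-diagonal correlation, where the network is empty) down to
#' `lambda_max * lambda_min_ratio`, fits the graphical lasso at every point
#' with warm starts, scores each fit by EBIC, and returns the minimizer.
#' Ties are broken toward the sparser model (larger penalty).
#'
#' @param corr a [corr_matrix()] with known `n`.
#' @param settings an [estimation_settings()].
#' @return a `ggm_network` with the selected `lambda`, `gamma` and `ebic`;
#'   the full path diagnostics are attached as attribute `"path"` (a data
#'   frame with `lambda`, `edge_count`, `ebic`).
#' @export
estimate_network <- function(corr, settings = estimation_settings()) {
  stopifnot(inherits(settings, "estimation_settings"))
  values <- corr$values
  off <- abs(values[upper.tri(values)])
  lambda_max <- max(off)
  lambdas <- if (lambda_max <= 0) 0 else
    exp(seq(log(lambda_max), log(lambda_max * settings$lambda_min_ratio),
            length.out = settings$n_lambda))
  fits <- glasso_path(corr, lambdas)
  ok <- which(fits$converged)
  if (length(ok) == 0)
    stop("no penalty value converged; cannot select a network")
  ebics <- vapply(ok, function(i)
    ebic_score(fits$networks[[i]], corr, gamma = settings$gamma), numeric(1))
  best <- ok[which.min(ebics)]  # path is in decreasing lambda: first minimum
  net <- fits$networks[[best]]  # is the sparsest among EBIC ties
  net$gamma <- settings$gamma
  net$ebic <- min(ebics)
  attr(net, "path") <- data.frame(
    lambda = lambdas[ok],
    edge_count = vapply(fits$networks[ok], function(x) x$edge_count,
                        integer(1)),
    ebic = ebics)
  net
}

#' Write a network as an edge list or full weight matrix
#'
#' @param network a `ggm_network`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list_csv <- function(network, path) {
  w <- network$weights
  idx <- which(upper.tri(w) & abs(w) > 1e-8, arr.ind = TRUE)
  d <- data.frame(node_a = network$labels[idx[, 1]],
                  node_b = network$labels[idx[, 2]],
                  weight = w[idx])
  d <- d[order(d$node_a, d$node_b), , drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list_csv
#' @export
write_weight_matrix_csv <- function(network, path) {
  d <- data.frame(item = network$labels, network$weights, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
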