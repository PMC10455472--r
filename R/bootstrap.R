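#' Bootstrap settings
#'
#' @param n_boot number of replicate samples (default 500, the standard
#'   choice for stability analysis of network dimensions).
#' @param seed master seed; replicate `b` uses the derived stream `seed + b`
#'   so runs are reproducible and trivially parallelizable.
#' @param confidence level for the confidence intervals on the dimension
#'   count (default 0.95).
#' @return a `bootstrap_settings` object.
#' @export
bootstrap_settings <- function(n_boot = 500L, seed = 1L, confidence = 0.95) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  structure(list(n_boot = as.integer(n_boot), seed = as.integer(seed),
                 confidence = confidence),
            class = "bootstrap_settings")
}

#' Construct a bootstrap ensemble from components
#'
#' Mostly used internally by [bootstrap_ega()], but exported so that
#' ensembles can be assembled by hand (e.g. for auditing the stability
#' algebra on known configurations).
#'
#' @param solutions list of [dimension_solution()]s, all over the same
#'   labels.
#' @param edges p x p x B array of replicate edge weights (optional; without
#'   it the typical network cannot be formed).
#' @param labels item labels.
#' @param n sample size used per replicate.
#' @param seed master seed.
#' @param n_redrawn number of replicates that had to be redrawn.
#' @return a `boot_ensemble`.
#' @export
boot_ensemble <- function(solutions, edges = NULL, labels = NULL, n = NA,
                          seed = NA, n_redrawn = 0L) {
  if (length(solutions) < 1) stop("ensemble must contain replicates")
  if (is.null(labels)) labels <- names(solutions[[1]])
  ok <- vapply(solutions, function(s) identical(names(s), labels), logical(1))
  if (!all(ok)) stop("all replicates must share the same label set")
  if (!is.null(edges))
    stopifnot(dim(edges)[1] == length(labels),
              dim(edges)[3] == length(solutions))
  structure(list(solutions = solutions, edges = edges, labels = labels,
                 n = n, seed = seed, n_redrawn = as.integer(n_redrawn)),
            class = "boot_ensemble")
}

#' @export
print.boot_ensemble <- function(x, ...) {
  counts <- vapply(x$solutions, n_dimensions, integer(1))
  cat("Bootstrap ensemble:", length(x$solutions), "replicates,",
      length(x$labels), "items\n")
  cat("  dimension counts:", paste(names(table(counts)), "->",
                                   table(counts), collapse = ", "), "\n")
  if (x$n_redrawn > 0) cat("  redrawn replicates:", x$n_redrawn, "\n")
  invisible(x)
}

#' Parametric bootstrap of exploratory graph analysis
#'
#' For each replicate, draws `n` observations from a multivariate normal
#' with covariance equal to the observed correlation matrix, recomputes the
#' sample correlation, and reruns the full EGA unit (penalty path, EBIC
#' selection, Walktrap). The result is a sampling distribution of networks
#' and dimension solutions. Replicates whose estimation fails even after
#' positive-semi-definite repair are redrawn from a fresh stream; if more
#' than 10% of replicates fail the run aborts, since the input is then too
#' ill-conditioned for the bootstrap to be meaningful.
#'
#' @param corr a [corr_matrix()] with known `n`.
#' @param settings an [estimation_settings()].
#' @param boot a [bootstrap_settings()].
#' @param steps Walktrap random-walk length.
#' @return a [boot_ensemble()].
#' @export
bootstrap_ega <- function(corr, settings = estimation_settings(),
                          boot = bootstrap_settings(), steps = 4L) {
  stopifnot(inherits(corr, "corr_matrix"))
  if (is.na(corr$n)) stop("correlation matrix must carry a sample size")
  p <- n_items(corr)
  sigma <- repair_correlation(corr$values, warn = FALSE)
  solutions <- vector("list", boot$n_boot)
  edges <- array(0, dim = c(p, p, boot$n_boot),
                 dimnames = list(corr$labels, corr$labels, NULL))
  n_redrawn <- 0L
  max_failures <- ceiling(0.10 * boot$n_boot)
  redraw_stream <- boot$seed + boot$n_boot  # fresh streams beyond the main ones
  for (b in seq_len(boot$n_boot)) {
    stream <- boot$seed + b
    repeat {
      fit <- tryCatch({
        set.seed(stream)
        x <- MASS::mvrnorm(corr$n, mu = rep(0, p), Sigma = sigma)
        rcorr <- corr_matrix(stats::cor(x), n = corr$n, labels = corr$labels)
        ega(rcorr, settings, steps = steps)
      }, error = function(e) e)
      if (!inherits(fit, "error")) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_failures)
        stop("more than 10% of bootstrap replicates failed; last error: ",
             conditionMessage(fit))
      redraw_stream <- redraw_stream + 1L
      stream <- redraw_stream
    }
    solutions[[b]] <- fit$solution
    edges[, , b] <- fit$network$weights
  }
  if (n_redrawn > 0)
    message("bootstrap: ", n_redrawn, " replicate(s) redrawn after failures")
  boot_ensemble(solutions, edges, labels = corr$labels, n = corr$n,
                seed = boot$seed, n_redrawn = n_redrawn)
}

#' Typical (median) network of a bootstrap ensemble
#'
#' Each edge of the typical network is the median of that edge across the
#' replicate networks (absent edges count as zero). Walktrap on the typical
#' network gives the typical, or median, dimension solution.
#'
#' @param ensemble a [boot_ensemble()] with stored edges.
#' @param steps Walktrap random-walk length.
#' @return list with `network` (a `ggm_network`; `lambda`/`ebic` are `NA`
#'   because the median network is not itself a fitted model) and `solution`.
#' @export
typical_network <- function(ensemble, steps = 4L) {
  if (is.null(ensemble$edges))
    stop("ensemble carries no edge weights; rerun the bootstrap with edges")
  med <- apply(ensemble$edges, c(1, 2), stats::median)
  net <- new_ggm_network(med, ensemble$labels, lambda = NA_real_,
                         gamma = NA_real_, ebic = NA_real_)
  list(network = net, solution = walktrap_dimensions(net, steps = steps))
}

#' Summarize the bootstrap distribution of the dimension count
#'
#' @param ensemble a [boot_ensemble()].
#' @param confidence CI level (default 0.95).
#' @return list of class `dimension_count_summary` with `frequencies`
#'   (named proportions summing to 1), `median`, `sd`, `ci` (normal
#'   approximation, `median +/- z * sd`) and `percentile_ci` (empirical
#'   quantiles of the replicate counts; endpoints are attained values).
#' @export
dimension_count_summary <- function(ensemble, confidence = 0.95) {
  counts <- vapply(ensemble$solutions, n_dimensions, integer(1))
  tab <- table(counts)
  freq <- as.numeric(tab) / length(counts)
  names(freq) <- names(tab)
  z <- stats::qnorm((1 + confidence) / 2)
  m <- stats::median(counts)
  s <- stats::sd(counts)
  alpha <- (1 - confidence) / 2
  pci <- stats::quantile(counts, c(alpha, 1 - alpha), type = 1, names = FALSE)
  structure(list(frequencies = freq, median = m, sd = s,
                 ci = c(lower = m - z * s, upper = m + z * s),
                 percentile_ci = c(lower = pci[1], upper = pci[2]),
                 confidence = confidence, n_boot = length(counts)),
            class = "dimension_count_summary")
}

#' @export
print.dimension_count_summary <- function(x, ...) {
  cat("Dimension counts over", x$n_boot, "bootstrap replicates\n")
  for (k in names(x$frequencies))
    cat(sprintf("  %s dimensions: %.1f%%\n", k, 100 * x$frequencies[[k]]))
  cat(sprintf("  median %.0f, sd %.2f, %d%% CI (%.2f-%.2f), percentile CI (%g-%g)\n",
              x$median, x$sd, round(100 * x$confidence),
              x$ci[1], x$ci[2], x$percentile_ci[1], x$percentile_ci[2]))
  invisible(x)
}

#' Write per-replicate dimension counts as CSV
#' @param ensemble a [boot_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_replicate_counts_csv <- function(ensemble, path) {
  counts <- vapply(ensemble$solutions, n_dimensions, integer(1))
  utils::write.csv(data.frame(replicate = seq_along(counts),
                              n_dimensions = counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
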