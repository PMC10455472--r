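#' Dimension solution: assignment of items to communities
#'
#' @param assignment named integer vector mapping each item label to a
#'   dimension index. Indices are renumbered to be contiguous from 1 in
#'   order of each dimension's first item, so solutions are comparable
#'   across runs regardless of the detector's internal numbering.
#' @return a `dimension_solution`: named integer vector with attribute
#'   `n_dims`.
#' @export
dimension_solution <- function(assignment) {
  if (is.null(names(assignment)) || anyNA(assignment))
    stop("assignment must be a fully named, complete integer vector")
  first <- !duplicated(assignment)
  remap <- stats::setNames(seq_len(sum(first)), assignment[first])
  out <- remap[as.character(assignment)]
  names(out) <- names(assignment)
  structure(as.integer(out), names = names(assignment),
            n_dims = length(remap), class = "dimension_solution")
}

#' @export
print.dimension_solution <- function(x, ...) {
  cat("Dimension solution:", attr(x, "n_dims"), "dimensions\n")
  for (d in seq_len(attr(x, "n_dims")))
    cat("  ", d, ": ", paste(names(x)[x == d], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Number of dimensions in a solution
#' @param solution a `dimension_solution`.
#' @return integer count.
#' @export
n_dimensions <- function(solution) attr(solution, "n_dims")

#' Item sets of each dimension
#' @param solution a `dimension_solution`.
#' @return list of character vectors, one per dimension.
#' @export
dimension_members <- function(solution) {
  lapply(seq_len(attr(solution, "n_dims")),
         function(d) names(solution)[solution == d])
}

#' Identify dimensions as Walktrap communities of the network
#'
#' Runs the Walktrap random-walk community algorithm on the graph whose edge
#' weights are the absolute partial correlations (the walk requires
#' non-negative weights; the signed weights stay available in the network
#' object). The merge level maximizing modularity is selected; on (numerical)
#' ties the cut with fewer communities wins. Nodes with no edges become
#' singleton dimensions, so an empty network yields p singletons.
#'
#' @param network a `ggm_network`.
#' @param steps random-walk length (default 4, the algorithm's canonical
#'   choice).
#' @return a [dimension_solution()].
#' @export
walktrap_dimensions <- function(network, steps = 4L) {
  w <- abs(network$weights)
  labels <- network$labels
  p <- length(labels)
  degree <- rowSums(w)
  isolated <- degree <= 1e-12
  membership <- rep(NA_integer_, p)
  if (any(!isolated)) {
    sub <- w[!isolated, !isolated, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    wc <- igraph::cluster_walktrap(g, steps = steps, merges = TRUE,
                                   modularity = TRUE, membership = TRUE)
    mods <- wc$modularity
    # modularity[i] is the score after i-1 merges; the last index attaining
    # the maximum (within numerical tolerance) has the fewest communities
    best <- max(which(mods >= max(mods) - 1e-12))
    membership[!isolated] <- as.integer(igraph::cut_at(wc, steps = best - 1L))
  }
  if (any(isolated)) {
    base <- max(membership, 0L, na.rm = TRUE)
    membership[isolated] <- base + seq_len(sum(isolated))
  }
  dimension_solution(stats::setNames(membership, labels))
}

#' Exploratory graph analysis: network estimation plus community detection
#'
#' The unit analysis applied to an observed sample and to every bootstrap
#' replicate: estimate the EBIC-selected graphical-lasso network, then count
#' its Walktrap communities. The number of communities estimates the number
#' of dimensions; the communities themselves give the item content of each
#' dimension.
#'
#' @param corr a [corr_matrix()] with known `n`.
#' @param settings an [estimation_settings()].
#' @param steps Walktrap random-walk length.
#' @return a list of class `ega_result` with elements `network`
#'   (`ggm_network`) and `solution` ([dimension_solution()]).
#' @examples
#' corr <- with_n(implied_correlation(wisc_preset("three_dim")), 1000)
#' fit <- ega(corr)
#' n_dimensions(fit$solution)
#' @export
ega <- function(corr, settings = estimation_settings(), steps = 4L) {
  network <- estimate_network(corr, settings)
  solution <- walktrap_dimensions(network, steps = steps)
  structure(list(network = network, solution = solution),
            class = "ega_result")
}

#' @export
print.ega_result <- function(x, ...) {
  print(x$network)
  print(x$solution)
  invisible(x)
}

#' Write a dimension solution as CSV
#' @param solution a `dimension_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  utils::write.csv(data.frame(item = names(solution),
                              dimension = as.integer(solution)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
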