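# Independent oracles and small fixture builders used across the suite.

# Partial correlation of variables i and j given all others, computed from
# the correlation matrix by the regression route: r_ij - s_i' S_rr^-1 s_j
# standardized by the residual variances. Independent of the precision-matrix
# inversion used by the package.
residual_partial <- function(R, i, j) {
  rest <- setdiff(seq_len(nrow(R)), c(i, j))
  if (length(rest) == 0) return(R[i, j])
  Srr <- R[rest, rest, drop = FALSE]
  si <- R[rest, i]
  sj <- R[rest, j]
  wi <- solve(Srr, si)
  wj <- solve(Srr, sj)
  (R[i, j] - sum(si * wj)) /
    sqrt((1 - sum(si * wi)) * (1 - sum(sj * wj)))
}

# Random well-conditioned correlation matrix (factor structure + ridge).
random_corr <- function(p, seed) {
  set.seed(seed)
  a <- matrix(rnorm(p * p), p)
  s <- crossprod(a) + p * diag(p)
  stats::cov2cor(s)
}

# All partitions of n elements as restricted-growth strings (rows).
all_set_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)  # current restricted growth string, 1-based
  rec <- function(k, maxval) {
    if (k > n) {
      out[[length(out) + 1L]] <<- rgs
      return(invisible())
    }
    for (v in seq_len(maxval + 1L)) {
      rgs[k] <<- v
      rec(k + 1L, max(maxval, v))
    }
  }
  rgs[1] <- 1L
  rec(2L, 1L)
  do.call(rbind, out)
}

# Newman modularity of a weighted undirected graph for a membership vector.
modularity_value <- function(W, membership) {
  m2 <- sum(W)  # twice the total edge weight for symmetric W with zero diag
  if (m2 == 0) return(0)
  k <- rowSums(W)
  B <- W - outer(k, k) / m2
  same <- outer(membership, membership, "==")
  sum(B[same]) / m2
}

# Best partition by exhaustive search (ties resolved to the first found).
exhaustive_best_partition <- function(W) {
  parts <- all_set_partitions(nrow(W))
  q <- apply(parts, 1, function(mb) modularity_value(W, mb))
  parts[which.max(q), ]
}

# Weighted 3-block toy network as a ggm_network.
block_network <- function(sizes, within, between, labels = NULL) {
  p <- sum(sizes)
  if (is.null(labels)) labels <- paste0("v", seq_len(p))
  block <- rep(seq_along(sizes), sizes)
  w <- matrix(between, p, p)
  for (b in seq_along(sizes))
    w[block == b, block == b] <- within
  diag(w) <- 0
  netdim:::new_ggm_network(w, labels, lambda = NA_real_, gamma = NA_real_,
                           ebic = NA_real_)
}

# Canonical form of a membership vector (order of first appearance) so
# partitions can be compared independently of label choice.
canon <- function(mb) {
  first <- !duplicated(mb)
  remap <- stats::setNames(seq_len(sum(first)), mb[first])
  unname(remap[as.character(mb)])
}

# Hand-assembled dimension solution from a list of item sets.
solution_from_sets <- function(sets) {
  assignment <- unlist(lapply(seq_along(sets), function(d)
    stats::setNames(rep(d, length(sets[[d]])), sets[[d]])))
  dimension_solution(assignment)
}

# Ensemble whose replicates are given as lists of item sets, all over the
# same labels (solutions are reordered to the shared label order).
ensemble_from_sets <- function(replicates, labels) {
  sols <- lapply(replicates, function(sets) {
    s <- solution_from_sets(sets)
    dimension_solution(stats::setNames(as.integer(s[labels]), labels))
  })
  boot_ensemble(sols, labels = labels, n = 100, seed = 0)
}
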