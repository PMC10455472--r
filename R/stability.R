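# Jaccard similarity of two item sets.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Align bootstrap dimensions to a reference solution
#'
#' Bootstrap replicates label their dimensions arbitrarily, so before item
#' placements can be aggregated each replicate's dimensions must be matched
#' to the empirical (reference) dimensions. Per replicate, a one-to-one
#' matching maximizing total Jaccard overlap of item sets is computed
#' (maximum-weight bipartite matching); replicate dimensions left unmatched,
#' or with zero overlap with every reference dimension, receive overflow
#' indices beyond the reference count. Overflow item sets are consolidated
#' across replicates so that recurring extra dimensions (e.g. a working
#' memory cluster that splits off intermittently) are reported as a single
#' stable column: a new overflow set joins an existing overflow column when
#' its Jaccard overlap with that column's first-seen prototype is at least
#' 0.5, and otherwise opens a new column.
#'
#' @param ensemble a [boot_ensemble()].
#' @param reference the empirical [dimension_solution()] to align to.
#' @return an `aligned_ensemble`: list with `map` (per replicate, an integer
#'   vector mapping replicate-dimension index to aligned column),
#'   `n_reference` (number of reference dimensions), `n_overflow`,
#'   `overflow_prototypes`, and the `reference` and `ensemble` used.
#' @export
align_dimensions <- function(ensemble, reference) {
  if (!setequal(names(reference), ensemble$labels))
    stop("ensemble and reference must share the same labels")
  ref_sets <- dimension_members(reference)
  k <- length(ref_sets)
  prototypes <- list()
  map <- vector("list", length(ensemble$solutions))
  for (b in seq_along(ensemble$solutions)) {
    rep_sets <- dimension_members(ensemble$solutions[[b]])
    m <- length(rep_sets)
    jac <- matrix(0, m, k)
    for (i in seq_len(m))
      for (j in seq_len(k))
        jac[i, j] <- jaccard(rep_sets[[i]], ref_sets[[j]])
    matched <- match_bipartite(jac)
    # overflow assignment: unmatched replicate dimensions, largest first
    unmatched <- which(is.na(matched))
    if (length(unmatched)) {
      sizes <- vapply(rep_sets[unmatched], length, integer(1))
      for (i in unmatched[order(-sizes)]) {
        js <- if (length(prototypes))
          vapply(prototypes, jaccard, numeric(1), b = rep_sets[[i]]) else numeric(0)
        if (length(js) && max(js) >= 0.5) {
          matched[i] <- k + which.max(js)
        } else {
          prototypes[[length(prototypes) + 1L]] <- rep_sets[[i]]
          matched[i] <- k + length(prototypes)
        }
      }
    }
    map[[b]] <- matched
  }
  structure(list(map = map, n_reference = k,
                 n_overflow = length(prototypes),
                 overflow_prototypes = prototypes,
                 reference = reference, ensemble = ensemble),
            class = "aligned_ensemble")
}

# Maximum-weight one-to-one matching of rows to columns of a non-negative
# score matrix; zero-score pairs are never matched. Returns, per row, the
# matched column index or NA.
match_bipartite <- function(scores) {
  m <- nrow(scores)
  k <- ncol(scores)
  idx <- which(scores > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(rep(NA_integer_, m))
  g <- igraph::make_empty_graph(n = m + k, directed = FALSE)
  g <- igraph::add_edges(g, rbind(idx[, 1], m + idx[, 2]))
  igraph::V(g)$type <- c(rep(FALSE, m), rep(TRUE, k))
  res <- igraph::max_bipartite_match(g, weights = scores[idx])
  out <- res$matching[seq_len(m)]
  ifelse(is.na(out), NA_integer_, out - m)
}

#' Item stability: where does each item land across replicates?
#'
#' Entry `(i, d)` is the fraction of replicates in which item `i` is placed
#' in aligned dimension `d` (reference dimensions first, then any overflow
#' columns). Because every item lands in exactly one replicate dimension and
#' every replicate dimension maps to exactly one column, each row sums to 1.
#' An item is *stable* when its proportion in its own reference dimension is
#' at least `threshold`.
#'
#' @param aligned an [align_dimensions()] result.
#' @param threshold stability cutoff (default 0.70).
#' @return list of class `item_stability` with `proportions` (item x column
#'   matrix), `own` (named vector: each item's proportion in its reference
#'   dimension), `unstable_items`, `threshold`.
#' @export
item_stability <- function(aligned, threshold = 0.70) {
  ens <- aligned$ensemble
  ref <- aligned$reference
  labels <- names(ref)
  ncol_total <- aligned$n_reference + aligned$n_overflow
  cols <- c(paste0("dim", seq_len(aligned$n_reference)),
            if (aligned$n_overflow)
              paste0("dim", aligned$n_reference + seq_len(aligned$n_overflow)))
  counts <- matrix(0, length(labels), ncol_total,
                   dimnames = list(labels, cols))
  nb <- length(ens$solutions)
  for (b in seq_len(nb)) {
    sol <- ens$solutions[[b]]
    dest <- aligned$map[[b]][as.integer(sol)]  # per-item aligned column
    ij <- cbind(match(names(sol), labels), dest)
    counts[ij] <- counts[ij] + 1
  }
  prop <- counts / nb
  own <- prop[cbind(seq_along(labels), as.integer(ref[labels]))]
  names(own) <- labels
  structure(list(proportions = prop, own = own,
                 unstable_items = labels[own < threshold],
                 threshold = threshold),
            class = "item_stability")
}

#' @export
print.item_stability <- function(x, ...) {
  cat("Item stability (own-dimension proportion, threshold ",
      x$threshold, "):\n", sep = "")
  print(round(x$own, 3))
  if (length(x$unstable_items))
    cat("Unstable items:", paste(x$unstable_items, collapse = ", "), "\n")
  else cat("All items stable.\n")
  invisible(x)
}

#' Structural consistency: exact recovery of each dimension
#'
#' For each reference dimension (an item set), the fraction of replicates
#' containing a dimension with exactly that item set. Computed by set
#' equality, independent of any alignment; exact recovery of a set implies
#' that each member was placed with it, so a dimension's consistency can
#' never exceed the smallest own-dimension item stability of its members.
#'
#' @param ensemble a [boot_ensemble()].
#' @param reference the empirical [dimension_solution()].
#' @return named numeric vector, one proportion per reference dimension.
#' @export
structural_consistency <- function(ensemble, reference) {
  ref_sets <- dimension_members(reference)
  nb <- length(ensemble$solutions)
  hits <- numeric(length(ref_sets))
  for (b in seq_len(nb)) {
    rep_sets <- dimension_members(ensemble$solutions[[b]])
    for (d in seq_along(ref_sets))
      if (any(vapply(rep_sets, setequal, logical(1), y = ref_sets[[d]])))
        hits[d] <- hits[d] + 1
  }
  stats::setNames(hits / nb, paste0("dim", seq_along(ref_sets)))
}

#' Full stability report for a bootstrap ensemble
#'
#' Combines dimension alignment, item stability and structural consistency,
#' and checks the internal algebra: item-stability rows sum to 1 and each
#' dimension's structural consistency is bounded by its members' own-
#' dimension stabilities.
#'
#' @param ensemble a [boot_ensemble()].
#' @param reference the empirical [dimension_solution()].
#' @param item_threshold item-stability cutoff (default 0.70).
#' @param dimension_threshold structural-consistency cutoff (default 0.75).
#' @return list of class `stability_report` with `item_stability`,
#'   `structural_consistency`, `unstable_items`, `unstable_dimensions`,
#'   thresholds and the alignment.
#' @export
stability_report <- function(ensemble, reference, item_threshold = 0.70,
                             dimension_threshold = 0.75) {
  aligned <- align_dimensions(ensemble, reference)
  items <- item_stability(aligned, threshold = item_threshold)
  sc <- structural_consistency(ensemble, reference)
  rowsum_err <- max(abs(rowSums(items$proportions) - 1))
  if (rowsum_err > 1e-12)
    stop("internal error: item-stability rows do not sum to 1 (max error ",
         format(rowsum_err), ")")
  for (d in seq_along(sc)) {
    members <- names(reference)[reference == d]
    if (sc[d] > min(items$own[members]) + 1e-12)
      stop("internal error: structural consistency of dimension ", d,
           " exceeds its members' item stability")
  }
  structure(list(item_stability = items,
                 structural_consistency = sc,
                 unstable_items = items$unstable_items,
                 unstable_dimensions = names(sc)[sc < dimension_threshold],
                 item_threshold = item_threshold,
                 dimension_threshold = dimension_threshold,
                 alignment = aligned),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  print(x$item_stability)
  cat("Structural consistency (threshold ", x$dimension_threshold, "):\n",
      sep = "")
  print(round(x$structural_consistency, 3))
  invisible(x)
}

#' Write stability tables as CSV
#'
#' @param report a [stability_report()].
#' @param items_path CSV for the item x dimension proportion matrix.
#' @param dims_path CSV for the per-dimension consistencies.
#' @return invisibly, `c(items_path, dims_path)`.
#' @export
write_stability_csv <- function(report, items_path, dims_path) {
  prop <- report$item_stability$proportions
  utils::write.csv(data.frame(item = rownames(prop), prop,
                              check.names = FALSE),
                   items_path, row.names = FALSE, quote = FALSE)
  sc <- report$structural_consistency
  utils::write.csv(data.frame(dimension = names(sc), consistency = sc),
                   dims_path, row.names = FALSE, quote = FALSE)
  invisible(c(items_path, dims_path))
}
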