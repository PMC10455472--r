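#' Specify a correlated common-factor model
#'
#' Defines the population model used by the simulator: standardized
#' indicators, each with one primary loading, an optional set of
#' cross-loadings, factor correlations `Phi`, and uniquenesses set to
#' `1 - communality` so every indicator has unit variance. The implied
#' population correlation matrix is `Sigma = Lambda Phi Lambda' + Theta`.
#'
#' @param loadings either a p x k loading matrix `Lambda` (rows = items,
#'   columns = factors), or a list of character vectors giving the items of
#'   each factor, in which case every primary loading equals
#'   `primary_loading`.
#' @param phi k x k factor correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite). Default: identity (orthogonal factors).
#' @param cross_loadings optional data frame with columns `item`, `factor`,
#'   `loading` declaring secondary loadings; `factor` may be a name or index.
#' @param primary_loading scalar loading used when `loadings` is given as
#'   item lists (default 0.70, a strong indicator in cognitive batteries).
#' @param labels item names; required when `loadings` is an unnamed matrix.
#' @param factor_names optional factor names.
#' @return An object of class `fm_spec` with elements `lambda`, `phi`,
#'   `labels`, `factor_names`, `primary` (named vector: primary factor of
#'   each item) and `cross_loadings`.
#' @examples
#' spec <- factor_model_spec(
#'   loadings = list(F1 = c("a", "b", "c"), F2 = c("d", "e", "f")),
#'   phi = matrix(c(1, 0.5, 0.5, 1), 2))
#' implied_correlation(spec)
#' @export
factor_model_spec <- function(loadings, phi = NULL, cross_loadings = NULL,
                              primary_loading = 0.70, labels = NULL,
                              factor_names = NULL) {
  if (is.list(loadings) && !is.data.frame(loadings)) {
    items <- unlist(loadings, use.names = FALSE)
    if (anyDuplicated(items))
      stop("an item may have only one primary factor; duplicated: ",
           paste(unique(items[duplicated(items)]), collapse = ", "))
    k <- length(loadings)
    if (is.null(factor_names))
      factor_names <- if (!is.null(names(loadings))) names(loadings)
                      else paste0("F", seq_len(k))
    lambda <- matrix(0, length(items), k,
                     dimnames = list(items, factor_names))
    for (f in seq_len(k))
      lambda[loadings[[f]], f] <- primary_loading
    labels <- items
  } else {
    lambda <- as.matrix(loadings)
    if (is.null(labels)) labels <- rownames(lambda)
    if (is.null(labels)) stop("labels required when the loading matrix is unnamed")
    if (is.null(factor_names)) factor_names <- colnames(lambda)
    if (is.null(factor_names)) factor_names <- paste0("F", seq_len(ncol(lambda)))
    dimnames(lambda) <- list(labels, factor_names)
  }
  k <- ncol(lambda)
  if (is.null(phi)) phi <- diag(k)
  phi <- as.matrix(phi)
  if (!isTRUE(all.equal(phi, t(phi), tolerance = 1e-12)))
    stop("phi must be symmetric")
  if (max(abs(diag(phi) - 1)) > 1e-12)
    stop("phi must have a unit diagonal")
  ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("phi is not positive semi-definite (min eigenvalue ",
         format(min(ev), digits = 3), ")")
  dimnames(phi) <- list(factor_names, factor_names)

  primary <- apply(abs(lambda), 1, function(r) {
    nz <- which(r > 0)
    if (length(nz) == 0) NA_integer_ else nz[which.max(r[nz])]
  })

  if (!is.null(cross_loadings)) {
    cross_loadings <- as.data.frame(cross_loadings)
    stopifnot(all(c("item", "factor", "loading") %in% names(cross_loadings)))
    for (i in seq_len(nrow(cross_loadings))) {
      it <- as.character(cross_loadings$item[i])
      f <- cross_loadings$factor[i]
      f <- if (is.character(f) || is.factor(f)) match(as.character(f), factor_names)
           else as.integer(f)
      if (is.na(f) || !(it %in% labels))
        stop("cross-loading refers to unknown item or factor: row ", i)
      lambda[it, f] <- cross_loadings$loading[i]
    }
  }

  structure(list(lambda = lambda, phi = phi, labels = labels,
                 factor_names = factor_names, primary = primary,
                 cross_loadings = cross_loadings),
            class = "fm_spec")
}

#' @export
print.fm_spec <- function(x, ...) {
  cat("Factor model:", length(x$labels), "items,",
      length(x$factor_names), "factors\n")
  cat("Primary blocks:\n")
  for (f in seq_along(x$factor_names)) {
    members <- x$labels[x$primary == f & !is.na(x$primary)]
    cat("  ", x$factor_names[f], ": ", paste(members, collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$cross_loadings))
    cat("Cross-loadings:", nrow(x$cross_loadings), "\n")
  invisible(x)
}

#' Population correlation matrix implied by a factor model
#'
#' Computes `Sigma = Lambda Phi Lambda' + Theta` with the diagonal uniqueness
#' matrix `Theta = I - diag(Lambda Phi Lambda')`, i.e. indicators are
#' standardized. Communalities above 1 (over-loaded items) are rejected with
#' a diagnostic naming the item.
#'
#' @param spec an [factor_model_spec()] object.
#' @return a [corr_matrix()] with `n = Inf` replaced by a nominal attribute —
#'   the population matrix carries no sample size, so `n` must be supplied
#'   downstream; here it is stored as `NA` and the caller attaches one via
#'   [with_n()].
#' @export
implied_correlation <- function(spec) {
  common <- spec$lambda %*% spec$phi %*% t(spec$lambda)
  h2 <- diag(common)
  bad <- which(h2 > 1 + 1e-12)
  if (length(bad))
    stop("communality exceeds 1 for item(s) ",
         paste(spec$labels[bad], collapse = ", "),
         " (uniqueness would be negative)")
  sigma <- common
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("implied matrix is not positive semi-definite")
  dimnames(sigma) <- list(spec$labels, spec$labels)
  out <- list(values = (sigma + t(sigma)) / 2, labels = spec$labels, n = NA_integer_)
  class(out) <- "corr_matrix"
  out
}

#' Attach a sample size to a population correlation matrix
#'
#' @param corr a `corr_matrix` (typically from [implied_correlation()]).
#' @param n the sample size to record.
#' @return the matrix with `n` set.
#' @export
with_n <- function(corr, n) {
  corr_matrix(corr$values, n = n, labels = corr$labels)
}

#' Draw multivariate-normal scores from a factor model
#'
#' Samples `n` independent observations from `N(0, Sigma)` where `Sigma` is
#' the model-implied correlation matrix. Reproducible bit-for-bit for a fixed
#' `(spec, n, seed)`.
#'
#' @param spec an [factor_model_spec()].
#' @param n number of observations (>= 2).
#' @param seed integer seed for the random stream.
#' @return An object of class `synthetic_dataset`: list with `scores`
#'   (n x p matrix), `labels`, `spec`, `n`, `seed`.
#' @export
sample_scores <- function(spec, n, seed) {
  if (n < 2) stop("n must be at least 2")
  sigma <- implied_correlation(spec)$values
  set.seed(as.integer(seed))
  x <- MASS::mvrnorm(n, mu = rep(0, nrow(sigma)), Sigma = sigma)
  colnames(x) <- spec$labels
  structure(list(scores = x, labels = spec$labels, spec = spec,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", x$n, "observations x", length(x$labels),
      "items (seed", x$seed, ")\n")
  invisible(x)
}

#' Write simulated scores as CSV
#' @param dataset a `synthetic_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset$scores), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# The 15 subtest labels of a Wechsler-style intelligence battery.
wisc_labels <- c("SI", "VO", "IN", "CO",      # verbal comprehension
                 "BD", "VP",                  # visual-spatial
                 "MR", "FW", "AR",            # fluid reasoning
                 "DS", "PS", "LN",            # working memory
                 "CD", "SS", "CA")            # processing speed

#' Preset factor models emulating a 15-subtest cognitive battery
#'
#' Ready-made [factor_model_spec()]s over the 15 standard subtest labels of a
#' Wechsler-style children's intelligence battery (SI, VO, IN, CO, BD, VP,
#' MR, FW, AR, DS, PS, LN, CD, SS, CA). All presets produce a positive
#' manifold with pairwise implied correlations inside `[0, 0.75]`, the range
#' typical of published standardization samples.
#'
#' * `three_dim` — three clearly separated dimensions: verbal comprehension
#'   (SI, VO, IN, CO), a broad perceptual-reasoning block (BD, VP, MR, FW,
#'   AR, DS, PS, LN) and processing speed (CD, SS, CA).
#' * `five_dim` — the five-factor publisher model: VC, VS (BD, VP), FR (MR,
#'   FW, AR), WM (DS, PS, LN), speed (CD, SS, CA).
#' * `five_dim_with_crossloaders` — the five-factor model plus balanced
#'   cross-loadings (0.45 primary / 0.45 secondary) on the six subtests that
#'   behave multidimensionally in standardization data: FW, AR, DS, PS, LN,
#'   CA. These items have no single well-defined home dimension, which is
#'   exactly the instability the bootstrap is designed to expose.
#'
#' @param structure_kind one of `"three_dim"`, `"five_dim"`,
#'   `"five_dim_with_crossloaders"`.
#' @return an `fm_spec`.
#' @examples
#' spec <- wisc_preset("three_dim")
#' range(implied_correlation(spec)$values[upper.tri(diag(15))])
#' @export
wisc_preset <- function(structure_kind = c("three_dim", "five_dim",
                                           "five_dim_with_crossloaders")) {
  structure_kind <- match.arg(structure_kind)
  if (structure_kind == "three_dim") {
    blocks <- list(VC = c("SI", "VO", "IN", "CO"),
                   PR = c("BD", "VP", "MR", "FW", "AR", "DS", "PS", "LN"),
                   SP = c("CD", "SS", "CA"))
    phi <- matrix(c(1.00, 0.50, 0.30,
                    0.50, 1.00, 0.35,
                    0.30, 0.35, 1.00), 3, byrow = TRUE)
    return(factor_model_spec(blocks, phi = phi, primary_loading = 0.70))
  }
  blocks <- list(VC = c("SI", "VO", "IN", "CO"),
                 VS = c("BD", "VP"),
                 FR = c("MR", "FW", "AR"),
                 WM = c("DS", "PS", "LN"),
                 SP = c("CD", "SS", "CA"))
  # positive-manifold factor correlations: the neighbouring perceptual
  # abilities (VS-FR) correlate most strongly — the pair the battery
  # struggles to separate — while the verbal dimension stands further apart
  phi <- matrix(c(1.00, 0.30, 0.20, 0.15, 0.25,
                  0.30, 1.00, 0.60, 0.30, 0.30,
                  0.20, 0.60, 1.00, 0.20, 0.30,
                  0.15, 0.30, 0.20, 1.00, 0.45,
                  0.25, 0.30, 0.30, 0.45, 1.00), 5, byrow = TRUE)
  if (structure_kind == "five_dim")
    return(factor_model_spec(blocks, phi = phi, primary_loading = 0.70))
  # crossloaders: primary reduced to 0.45 plus a balanced 0.45 secondary on
  # the verbal dimension, emulating the verbally mediated multidimensionality
  # these subtests display in standardization data (each is torn between its
  # home ability and the verbal cluster, so bootstrap placements flip)
  cross <- data.frame(
    item    = c("FW", "AR", "DS", "PS", "LN", "CA"),
    factor  = c("VC", "VC", "VC", "VC", "VC", "VC"),
    loading = 0.45)
  spec <- factor_model_spec(blocks, phi = phi, primary_loading = 0.70)
  lam <- spec$lambda
  for (i in seq_len(nrow(cross))) {
    it <- cross$item[i]
    lam[it, spec$primary[it]] <- 0.45
    lam[it, cross$factor[i]] <- 0.45
  }
  out <- factor_model_spec(lam, phi = phi, labels = rownames(lam),
                           factor_names = colnames(lam))
  # keep the primary-factor bookkeeping from the block structure: for the
  # balanced 0.45/0.45 items the declared block, not the tie-break, is primary
  out$primary <- spec$primary
  out$cross_loadings <- cross
  out
}
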