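test_that("precision-based partials match closed-form and regression oracles", {
  # independence: identity in, all-zero partials out
  expect_equal(partial_correlations(corr_matrix(diag(4), n = 50)),
               matrix(0, 4, 4), ignore_attr = TRUE)

  # 3 x 3 exchangeable 0.5: first-order formula gives exactly 1/3
  m <- matrix(0.5, 3, 3); diag(m) <- 1
  pc <- partial_correlations(corr_matrix(m, n = 100))
  expect_equal(pc[upper.tri(pc)], rep(1 / 3, 3))

  # random matrices against the regression-residual oracle
  for (seed in 1:25) {
    p <- sample(4:6, 1)
    R <- random_corr(p, seed)
    pc <- partial_correlations(corr_matrix(R, n = 100))
    for (i in 1:(p - 1)) for (j in (i + 1):p)
      expect_equal(pc[i, j], residual_partial(R, i, j), tolerance = 1e-10)
  }
})

test_that("partial correlations are permutation-equivariant", {
  R <- random_corr(6, 99)
  rownames(R) <- colnames(R) <- letters[1:6]
  pc <- partial_correlations(corr_matrix(R, n = 200))
  perm <- c(4, 2, 6, 1, 3, 5)
  pc_perm <- partial_correlations(
    corr_matrix(R[perm, perm], n = 200))
  expect_equal(pc_perm, pc[perm, perm], tolerance = 1e-12)
})

test_that("singular input errors; near-singular input is repaired", {
  m <- matrix(1, 3, 3)  # rank 1
  expect_error(partial_correlations(corr_matrix(m, n = 100), repair = FALSE),
               "singular")
  r <- repair_correlation(m, warn = FALSE)
  expect_equal(diag(r), rep(1, 3))
  expect_gt(min(eigen(r, symmetric = TRUE)$values), 0)
})

test_that("graphical lasso limits: full shrinkage and the lambda = 0 oracle", {
  spec <- wisc_preset("three_dim")
  corr <- with_n(implied_correlation(spec), 1000)
  lambda_max <- max(abs(corr$values[upper.tri(corr$values)]))

  empty <- glasso_fit(corr, lambda_max)
  expect_equal(empty$edge_count, 0L)
  expect_equal(empty$weights, matrix(0, 15, 15), ignore_attr = TRUE)

  free <- glasso_fit(corr, 0)
  expect_equal(free$weights, partial_correlations(corr), tolerance = 1e-4)

  # small random inputs too
  for (seed in 1:5) {
    R <- random_corr(5, seed + 200)
    cm <- corr_matrix(R, n = 500)
    expect_equal(glasso_fit(cm, 0)$weights, partial_correlations(cm),
                 tolerance = 1e-4)
    lm <- max(abs(R[upper.tri(R)]))
    expect_equal(glasso_fit(cm, lm * 1.01)$edge_count, 0L)
  }
})

test_that("edge count never increases along the penalty path", {
  corr <- with_n(implied_correlation(wisc_preset("five_dim")), 800)
  net <- estimate_network(corr)
  path <- attr(net, "path")
  # path rows are ordered from largest to smallest lambda
  expect_true(all(diff(order(path$lambda, decreasing = TRUE)) == 1))
  expect_true(all(diff(path$edge_count) >= 0))
})

test_that("no edges cross the blocks of a block-diagonal correlation matrix", {
  spec <- factor_model_spec(list(A = letters[1:4], B = letters[5:8]),
                            primary_loading = 0.7)  # orthogonal factors
  corr <- with_n(implied_correlation(spec), 1000)
  net <- glasso_fit(corr, 0.01)
  cross_block <- net$weights[1:4, 5:8]
  expect_equal(max(abs(cross_block)), 0)
  expect_gt(min(abs(net$weights[1:4, 1:4][upper.tri(diag(4))])), 0)
})

test_that("EBIC follows its closed form and penalizes density", {
  corr <- with_n(implied_correlation(wisc_preset("three_dim")), 500)
  net <- glasso_fit(corr, 0.05, gamma = 0.5)

  # gamma = 0 reduces to BIC: difference is exactly 4 * gamma * E * log p
  b0 <- ebic_score(net, corr, gamma = 0)
  b5 <- ebic_score(net, corr, gamma = 0.5)
  expect_equal(b5 - b0, 4 * 0.5 * net$edge_count * log(15))
  expect_gt(b5, b0)  # monotone in gamma when E > 0

  # direct recomputation of the likelihood term
  theta <- net$precision
  ll <- (corr$n / 2) * (determinant(theta)$modulus[1] -
                          sum(corr$values * theta))
  expect_equal(b0, -2 * ll + net$edge_count * log(corr$n))
})

test_that("EBIC selection recovers a sparse truth against a dense competitor", {
  # two independent 3-cliques; the saturated model carries 9 spurious edges
  spec <- factor_model_spec(list(A = letters[1:3], B = letters[4:6]),
                            primary_loading = 0.7)
  x <- sample_scores(spec, 2000, seed = 5)
  corr <- corr_from_scores(x$scores)
  sel <- estimate_network(corr)
  dense <- glasso_fit(corr, 0.001)
  expect_lt(sel$edge_count, dense$edge_count)
  expect_lt(sel$ebic, ebic_score(dense, corr, gamma = 0.5))
  # every true within-block edge is retained by the selected model
  within <- rbind(t(combn(1:3, 2)), t(combn(4:6, 2)))
  expect_true(all(abs(sel$weights[within]) > 1e-8))
})

test_that("model selection is deterministic and minimizes EBIC on the path", {
  corr <- with_n(implied_correlation(wisc_preset("three_dim")), 1000)
  n1 <- estimate_network(corr)
  n2 <- estimate_network(corr)
  expect_identical(n1$lambda, n2$lambda)
  expect_identical(n1$weights, n2$weights)
  path <- attr(n1, "path")
  expect_true(all(n1$ebic <= path$ebic + 1e-9))
  # identity input: empty network selected
  id <- corr_matrix(diag(5), n = 100)
  expect_equal(estimate_network(id)$edge_count, 0L)
})

test_that("network export formats agree with the weights", {
  corr <- with_n(implied_correlation(wisc_preset("three_dim")), 500)
  net <- estimate_network(corr)
  f <- tempfile(fileext = ".csv")
  write_edge_list_csv(net, f)
  edges <- utils::read.csv(f)
  expect_equal(nrow(edges), net$edge_count)
  for (k in seq_len(min(5, nrow(edges))))
    expect_equal(edges$weight[k],
                 net$weights[edges$node_a[k], edges$node_b[k]],
                 tolerance = 1e-6)
  f2 <- tempfile(fileext = ".csv")
  write_weight_matrix_csv(net, f2)
  m <- utils::read.csv(f2, check.names = FALSE)
  expect_equal(as.matrix(m[, -1]), net$weights, ignore_attr = TRUE,
               tolerance = 1e-6)
})
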