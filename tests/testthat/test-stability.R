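wisc15 <- c("SI", "VO", "IN", "CO", "BD", "VP", "MR", "FW", "AR",
            "DS", "PS", "LN", "CD", "SS", "CA")

test_that("alignment is invariant to how replicate dimensions are numbered", {
  labels <- letters[1:9]
  ref_sets <- list(c("a", "b", "c"), c("d", "e", "f"), c("g", "h", "i"))
  ref <- solution_from_sets(ref_sets)
  # same partition, dimensions listed in a different order: numbering is
  # canonical (first-occurrence), so each dimension matches its counterpart
  ens <- ensemble_from_sets(list(ref_sets[c(3, 1, 2)]), labels)
  aligned <- align_dimensions(ens, ref)
  expect_equal(aligned$map[[1]], c(1L, 2L, 3L))
  expect_equal(aligned$n_overflow, 0L)

  # crossed content: replicate dim 1 is {a,d,e,f}, whose best Jaccard match
  # is reference dim 2 {d,e,f}; replicate dim 2 {b,c} matches reference 1
  crossed <- list(c("a", "d", "e", "f"), c("b", "c"), c("g", "h", "i"))
  aligned2 <- align_dimensions(ensemble_from_sets(list(crossed), labels), ref)
  expect_equal(aligned2$map[[1]], c(2L, 1L, 3L))
})

test_that("a moved item leaves all dimensions matched to their counterparts", {
  labels <- letters[1:9]
  ref <- solution_from_sets(list(c("a", "b", "c"), c("d", "e", "f"),
                                 c("g", "h", "i")))
  moved <- list(c("a", "b"), c("d", "e", "f", "c"), c("g", "h", "i"))
  aligned <- align_dimensions(ensemble_from_sets(list(moved), labels), ref)
  expect_equal(aligned$map[[1]], c(1L, 2L, 3L))
})

test_that("split-off dimensions flow to a stable overflow index", {
  # reference merges working memory into one big dimension; replicates
  # split {DS, LN, PS, AR} off -> overflow column n_dims + 1
  ref <- solution_from_sets(list(
    c("SI", "VO", "IN", "CO", "LN"),
    c("BD", "VP", "MR", "FW", "AR", "DS", "PS"),
    c("CD", "SS", "CA")))
  split_rep <- list(
    c("SI", "VO", "IN", "CO"),
    c("BD", "VP", "MR", "FW"),
    c("DS", "LN", "PS", "AR"),
    c("CD", "SS", "CA"))
  ens <- ensemble_from_sets(list(split_rep, split_rep), wisc15)
  aligned <- align_dimensions(ens, ref)
  expect_equal(aligned$n_overflow, 1L)
  expect_equal(aligned$map[[1]][3], 4L)   # the split-off set -> dimension 4
  expect_equal(aligned$map[[2]][3], 4L)   # same index in every replicate
  expect_setequal(aligned$overflow_prototypes[[1]],
                  c("DS", "LN", "PS", "AR"))
})

test_that("item stability reproduces a hand-built placement distribution", {
  labels <- c("X", "a", "b", "c", "d", "e")
  ref <- solution_from_sets(list(c("X", "a", "b"), c("c", "d"), "e"))
  rep_home <- list(c("X", "a", "b"), c("c", "d"), "e")         # X in dim 1
  rep_move <- list(c("a", "b"), c("c", "d", "X"), "e")         # X in dim 2
  rep_split <- list(c("a", "b"), c("c", "d"), "e", "X")        # X overflow
  reps <- c(replicate(65, rep_home, simplify = FALSE),
            replicate(21, rep_move, simplify = FALSE),
            replicate(14, rep_split, simplify = FALSE))
  ens <- ensemble_from_sets(reps, labels)
  rep <- stability_report(ens, ref)
  prop <- rep$item_stability$proportions
  expect_equal(prop["X", "dim1"], 0.65)
  expect_equal(prop["X", "dim2"], 0.21)
  expect_equal(prop["X", "dim4"], 0.14)
  expect_true("X" %in% rep$unstable_items)
  expect_false("a" %in% rep$unstable_items)
  expect_equal(rowSums(prop), rep(1, 6), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("structural consistency counts exact set recovery only", {
  labels <- wisc15
  ref <- solution_from_sets(list(
    setdiff(wisc15, c("CD", "SS", "CA", "SI", "VO")),
    c("SI", "VO"),
    c("CD", "SS", "CA")))
  intact <- list(setdiff(wisc15, c("CD", "SS", "CA", "SI", "VO")),
                 c("SI", "VO"), c("CD", "SS", "CA"))
  broken <- list(setdiff(wisc15, c("CD", "SS", "SI", "VO")),
                 c("SI", "VO"), c("CD", "SS"))
  reps <- c(replicate(7, intact, simplify = FALSE),
            replicate(3, broken, simplify = FALSE))
  sc <- structural_consistency(ensemble_from_sets(reps, labels), ref)
  expect_equal(unname(sc), c(0.7, 1.0, 0.7))
})

test_that("identical replicates give perfect stability everywhere", {
  ref <- solution_from_sets(list(letters[1:3], letters[4:6]))
  ens <- ensemble_from_sets(
    replicate(10, list(letters[1:3], letters[4:6]), simplify = FALSE),
    letters[1:6])
  rep <- stability_report(ens, ref)
  expect_equal(unname(rep$item_stability$own), rep(1, 6))
  expect_equal(unname(rep$structural_consistency), c(1, 1))
  expect_length(rep$unstable_items, 0)
})

test_that("stability metrics are invariant to replicate order", {
  corr <- with_n(implied_correlation(wisc_preset("five_dim_with_crossloaders")),
                 500)
  fit <- ega(corr)
  ens <- bootstrap_ega(corr, boot = bootstrap_settings(n_boot = 20, seed = 1))
  rev_ens <- boot_ensemble(rev(ens$solutions),
                           ens$edges[, , 20:1, drop = FALSE],
                           labels = ens$labels, n = ens$n, seed = ens$seed)
  r1 <- stability_report(ens, fit$solution)
  r2 <- stability_report(rev_ens, fit$solution)
  expect_equal(r1$item_stability$own, r2$item_stability$own)
  expect_equal(r1$structural_consistency, r2$structural_consistency)
})

test_that("consistency is bounded by member item stability on real runs", {
  corr <- with_n(implied_correlation(wisc_preset("five_dim_with_crossloaders")),
                 500)
  fit <- ega(corr)
  ens <- bootstrap_ega(corr, boot = bootstrap_settings(n_boot = 30, seed = 2))
  rep <- stability_report(ens, fit$solution)  # internal assertions also run
  own <- rep$item_stability$own
  for (d in seq_along(rep$structural_consistency)) {
    members <- names(fit$solution)[fit$solution == d]
    expect_lte(rep$structural_consistency[[d]], min(own[members]) + 1e-12)
  }
  expect_equal(rowSums(rep$item_stability$proportions),
               rep(1, 15), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("raising a planted cross-loading never improves own-dimension stability", {
  base <- wisc_preset("five_dim")
  grid <- c(0, 0.25, 0.45)
  own_fw <- vapply(grid, function(cl) {
    lam <- base$lambda
    if (cl > 0) {
      lam["FW", "FR"] <- 0.45
      lam["FW", "VC"] <- cl
    }
    spec <- factor_model_spec(lam, phi = base$phi, labels = rownames(lam))
    corr <- with_n(implied_correlation(spec), 500)
    fit <- ega(corr)
    ens <- bootstrap_ega(corr, boot = bootstrap_settings(n_boot = 30,
                                                         seed = 5))
    rep <- stability_report(ens, fit$solution)
    rep$item_stability$own[["FW"]]
  }, numeric(1))
  expect_true(all(diff(own_fw) <= 1e-12))
})
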