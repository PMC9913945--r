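test_that("probe filter keeps a label-matching feature and drops the probe", {
  kept_has_signal <- vapply(1:10, function(s) {
    tab <- toy_signal_table(n = 40, n_noise = 20, gap = 50, seed = s,
                            signal_name = "A")
    tab$A <- as.numeric(tab$group == "schizophrenia")  # A equals the label
    class(tab) <- c("feature_table", "data.frame")
    res <- probe_shap_filter(tab, model_spec("logreg", C = 1),
                             selection_config("probe_shap", probe_seed = s))
    expect_false("random_probe" %in% res$kept)
    "A" %in% res$kept
  }, logical(1))
  expect_true(all(kept_has_signal))
})

test_that("probe filter keeps almost nothing on pure noise", {
  near_empty <- vapply(1:10, function(s) {
    set.seed(s + 100)
    y <- sample(rep(c("healthy", "schizophrenia"), each = 15))
    tab <- toy_table(matrix(rnorm(30 * 20),
                            dimnames = list(NULL, paste0("n", 1:20)),
                            nrow = 30), y)
    # sparse model: on pure noise the lasso zeroes most coefficients, so
    # most features tie with the probe at zero importance and are dropped
    res <- probe_shap_filter(tab, model_spec("logreg", penalty = "l1",
                                             C = 0.1),
                             selection_config("probe_shap", probe_seed = s))
    length(res$kept) <= 2  # <= 10 % of 20 features
  }, logical(1))
  expect_gte(sum(near_empty), 9)
})

test_that("probe filter is column-order invariant up to set equality", {
  tab <- toy_signal_table(n = 40, n_noise = 8, gap = 6, seed = 3)
  cfg <- selection_config("probe_shap", probe_seed = 4)
  sp <- model_spec("logreg", C = 1)
  r1 <- probe_shap_filter(tab, sp, cfg)
  perm <- tab[, c("subject_id", "group", rev(feature_names(tab)))]
  class(perm) <- class(tab)
  r2 <- probe_shap_filter(perm, sp, cfg)
  expect_setequal(r1$kept, r2$kept)
})

test_that("forward SFS picks the separating feature first", {
  tab <- toy_signal_table(n = 40, n_noise = 6, gap = 8, seed = 2)
  res <- sequential_select(tab, model_spec("logreg", C = 1),
                           selection_config("sfs_forward"), "forward")
  expect_equal(res$kept[1], "f1")
  # its singleton inner-CV score is maximal over all singleton sets
  folds <- erpdx:::stratified_folds(table_groups(tab), 5, 1)
  singleton <- vapply(feature_names(tab), function(j) {
    erpdx:::score_feature_set(tab, j, model_spec("logreg", C = 1), folds,
                              "f1")
  }, numeric(1))
  expect_equal(names(which.max(singleton)), "f1")
})

test_that("backward SFS removes a duplicated feature without score loss", {
  # wide gap: either copy alone still separates, so the scores tie
  tab <- toy_signal_table(n = 30, n_noise = 0, gap = 10, seed = 5)
  tab$f1_copy <- tab$f1
  class(tab) <- c("feature_table", "data.frame")
  res <- sequential_select(tab, model_spec("logreg", C = 1),
                           selection_config("sfs_backward"), "backward")
  expect_length(res$kept, 1)
  expect_gte(utils::tail(res$trace, 1), res$trace[1])
})

test_that("backward SFS final score never falls below the full-set score", {
  tab <- toy_signal_table(n = 40, n_noise = 5, gap = 2, seed = 6)
  res <- sequential_select(tab, model_spec("logreg", C = 1),
                           selection_config("sfs_backward", max_steps = 3),
                           "backward")
  expect_gte(utils::tail(res$trace, 1), res$trace[1] - 1e-12)
  expect_true(all(res$kept %in% feature_names(tab)))
})

test_that("SFS respects the max_steps budget", {
  tab <- toy_signal_table(n = 30, n_noise = 10, gap = 10, seed = 7)
  res <- sequential_select(tab, model_spec("logreg", C = 1),
                           selection_config("sfs_backward", max_steps = 2),
                           "backward")
  expect_gte(length(res$kept), length(feature_names(tab)) - 2)
})

test_that("svd_reduce picks the smallest k reaching the variance cutoff", {
  set.seed(9)
  base <- rnorm(40)
  x <- sapply(1:10, function(i) base + rnorm(40, sd = 1e-3))
  colnames(x) <- paste0("d", 1:10)
  tab <- toy_table(x, rep(c("healthy", "schizophrenia"), each = 20))
  res <- svd_reduce(tab, selection_config("truncated_svd",
                                          svd_variance_frac = 0.9))
  expect_equal(res$projection$k, 1)
  expect_gte(res$projection$explained_frac, 0.9)
  # frac = 1 keeps the full spectrum
  res1 <- svd_reduce(tab, selection_config("truncated_svd",
                                           svd_variance_frac = 1))
  expect_equal(res1$projection$explained_frac, 1, tolerance = 1e-12)
  # held-out rows are projected with the training center/rotation
  z <- apply_svd(res, tab[1:3, ])
  expect_equal(nrow(z), 3)
  expect_equal(feature_names(z), "svd_1")
  expect_error(selection_config("truncated_svd", svd_variance_frac = 1.2))
})

test_that("probe_then_sfs runs SFS on the probe survivors", {
  tab <- toy_signal_table(n = 40, n_noise = 10, gap = 20, seed = 8)
  res <- erpdx:::run_selection(tab, model_spec("logreg", C = 1),
                               selection_config("probe_then_sfs",
                                                probe_seed = 8,
                                                max_steps = 2))
  expect_equal(res$strategy, "probe_then_sfs")
  expect_true("f1" %in% res$kept)
  expect_false("random_probe" %in% res$kept)
})

test_that("selection depends only on the rows it is given", {
  tab <- toy_signal_table(n = 40, n_noise = 4, gap = 5, seed = 10)
  cfg <- selection_config("sfs_backward", max_steps = 1)
  r1 <- sequential_select(tab, model_spec("logreg", C = 1), cfg, "backward")
  r2 <- sequential_select(tab, model_spec("logreg", C = 1), cfg, "backward")
  expect_identical(r1$kept, r2$kept)
})
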