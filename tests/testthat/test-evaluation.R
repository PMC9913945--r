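test_that("choose_threshold balances TPR and TNR against an exhaustive scan", {
  lab <- function(y) factor(ifelse(y == 1, "schizophrenia", "healthy"),
                            levels = erp_groups())
  # perfectly separated probabilities
  y <- lab(c(0, 0, 1, 1))
  thr <- choose_threshold(c(0.1, 0.2, 0.8, 0.9), y)
  m <- compute_metrics(c(0.1, 0.2, 0.8, 0.9), y, thr)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  # probabilities equal to labels
  y01 <- c(0, 1, 0, 1, 1)
  thr2 <- choose_threshold(y01, lab(y01))
  m2 <- compute_metrics(y01, lab(y01), thr2)
  expect_equal(abs(m2$sensitivity - m2$specificity), 0)
  # random instances: returned threshold attains the scan minimum
  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    y <- lab(rbinom(n, 1, 0.4))
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)
    thr <- choose_threshold(p, y)
    gap <- function(t) {
      pr <- p >= t
      abs(mean(pr[y == "schizophrenia"]) - mean(!pr[y == "healthy"]))
    }
    u <- sort(unique(p))
    cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    expect_lte(gap(thr), min(vapply(cand, gap, numeric(1))) + 1e-12)
  }
  expect_error(choose_threshold(c(0.2, 0.8), lab(c(1, 1))), "both classes")
})

test_that("compute_metrics matches ratio arithmetic and a reference AUC", {
  lab <- factor(rep(c("schizophrenia", "healthy"), c(68, 132)),
                levels = erp_groups())
  p <- c(rep(1, 62), rep(0, 6), rep(0, 121), rep(1, 11))
  m <- compute_metrics(p, lab, 0.5)
  expect_equal(m$sensitivity, 62 / 68)
  expect_equal(m$confusion[["tp"]], 62)
  expect_equal(m$confusion[["fn"]], 6)
  expect_equal(m$f1, 2 * 62 / (2 * 62 + 11 + 6))
  # ties get half credit; constant probabilities give AUC 0.5
  expect_equal(compute_metrics(rep(0.3, 200), lab, 0.5)$auc, 0.5)
  # perfect ranking
  expect_equal(compute_metrics(c(rep(0.9, 68), rep(0.1, 132)), lab, 0.5)$auc,
               1)
  # rank AUC equals pROC on random data
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:10) {
    y <- factor(sample(rep(erp_groups(), c(20, 15))), levels = erp_groups())
    pr <- round(runif(35), 1)
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = y, predictor = pr, levels = erp_groups(),
      direction = "<")))
    expect_equal(compute_metrics(pr, y, 0.5)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("cross_validate conserves subjects in the summed confusion matrix", {
  ds <- small_cohort(24, 16, seed = 21)
  pt <- grid_point(coarse_window_params(), model_spec("logreg", C = 1),
                   selection_config("none"), TRUE)
  rep <- cross_validate(ds, pt, cv_config(outer_folds = 5, seed = 3))
  cm <- rep$confusion
  expect_equal(sum(cm), 40)
  expect_equal(cm[["tp"]] + cm[["fn"]], 16)
  expect_equal(cm[["tn"]] + cm[["fp"]], 24)
  # mean/sd match recomputation from the stored per-fold values
  expect_equal(rep$metrics$mean, unname(rowMeans(rep$per_fold)))
  expect_equal(rep$metrics$sd, unname(apply(rep$per_fold, 1, sd)))
  for (mn in rep$metrics$metric) {
    i <- which(rep$metrics$metric == mn)
    expect_gte(rep$metrics$mean[i], min(rep$per_fold[i, ]))
    expect_lte(rep$metrics$mean[i], max(rep$per_fold[i, ]))
  }
})

test_that("every subject is tested exactly once and folds are stratified", {
  y <- factor(rep(erp_groups(), c(33, 17)), levels = erp_groups())
  folds <- erpdx:::stratified_folds(y, 5, 7)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 50)
  per_fold <- table(folds, y)
  expect_true(all(abs(per_fold[, "schizophrenia"] - 17 / 5) < 1.01))
  expect_error(erpdx:::stratified_folds(y, 20, 1), "minority")
})

test_that("training-fold fits are unchanged when held-out rows change", {
  ds <- small_cohort(18, 12, seed = 33)
  pt <- grid_point(coarse_window_params(), model_spec("logreg", C = 1),
                   selection_config("sfs_backward", inner_folds = 3,
                                    max_steps = 1), TRUE)
  cv <- cv_config(outer_folds = 3, seed = 9)
  rep1 <- cross_validate(ds, pt, cv)
  # scramble the ERPs of fold 1's test subjects only
  y <- factor(vapply(ds$subjects, function(s) s$group, character(1)),
              levels = erp_groups())
  folds <- erpdx:::stratified_folds(y, 3, cv$seed)
  ids <- vapply(ds$subjects, function(s) s$subject_id, character(1))
  ds2 <- scramble_subjects(ds, ids[folds == 1])
  rep2 <- cross_validate(ds2, pt, cv)
  f1a <- rep1$folds[[1]]
  f1b <- rep2$folds[[1]]
  expect_identical(f1b$kept, f1a$kept)
  expect_identical(f1b$threshold, f1a$threshold)
  expect_identical(f1b$scaler_digest, f1a$scaler_digest)
  expect_identical(f1b$model_digest, f1a$model_digest)
  # the held-out metrics do change
  expect_false(identical(f1b$metrics, f1a$metrics))
})

test_that("grid_search ranks deterministically and tolerates failures", {
  ds <- small_cohort(14, 10, seed = 41)
  pt <- grid_point(coarse_window_params(), model_spec("logreg", C = 1),
                   selection_config("none"), TRUE)
  res1 <- grid_search(ds, list(pt), cv_config(outer_folds = 3, seed = 2))
  expect_equal(res1$ranking$point, 1)
  res2 <- grid_search(ds, list(pt, pt), cv_config(outer_folds = 3, seed = 2))
  expect_equal(res2$results[[1]]$metrics, res2$results[[2]]$metrics)
  # a degenerate window set fails that point but not the search
  bad <- pt
  bad$window_params$ph <- window_params(4000, 100)
  res3 <- grid_search(ds, list(bad, pt), cv_config(outer_folds = 3, seed = 2))
  expect_s3_class(res3$results[[1]], "grid_failure")
  expect_equal(res3$ranking$point, 2)
  expect_error(grid_search(ds, list(bad), cv_config(outer_folds = 3)),
               "every grid point failed")
})
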