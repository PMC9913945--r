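# Cross-validated evaluation: stratified outer folds, per-fold pipeline
# fitting (scaler + selection + model on training rows only), balanced
# sensitivity/specificity thresholding on training-side out-of-fold
# predictions, fold-aggregated metrics and the summed confusion matrix;
# grid search over window parameters jointly with model hyperparameters.

#' Cross-validation configuration
#'
#' @param outer_folds Number of outer folds K (default 10); must not
#'   exceed the minority-class count.
#' @param stratified Stratify folds by group (default `TRUE`).
#' @param seed Fold-shuffle seed.
#' @param threshold_folds Inner folds used to collect the training-side
#'   out-of-fold predictions on which the decision threshold is chosen
#'   (default 5).
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10, stratified = TRUE, seed = 1,
                      threshold_folds = 5) {
  stopifnot(outer_folds >= 2, threshold_folds >= 2)
  structure(list(outer_folds = as.integer(outer_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed),
                 threshold_folds = as.integer(threshold_folds)),
            class = "cv_config")
}

#' One point of the pipeline grid
#'
#' A fully explicit pipeline configuration: window parameters per
#' condition, selection strategy, model spec, and whether behavioral
#' columns enter the table.
#'
#' @param window_params A `window_param_set`.
#' @param model A [model_spec()].
#' @param selection A [selection_config()].
#' @param include_behavior Append behavioral columns (default `TRUE`).
#' @return Object of class `grid_point`.
#' @export
grid_point <- function(window_params = default_window_params(),
                       model = model_spec("svm", C = 1 / 3),
                       selection = selection_config("none"),
                       include_behavior = TRUE) {
  structure(list(window_params = window_params, model = model,
                 selection = selection,
                 include_behavior = isTRUE(include_behavior)),
            class = "grid_point")
}

#' The smoke grid point
#'
#' A single fast configuration used for end-to-end recovery runs: coarse
#' one-window-per-signal window parameters, RBF SVM with `C = 1/3` and
#' scaled gamma, backward sequential selection on 3 inner folds with a
#' 2-step budget, standard scaling, behavior on.
#'
#' @return A [grid_point()].
#' @export
smoke_grid_point <- function() {
  grid_point(
    window_params = coarse_window_params(),
    model = model_spec("svm", C = 1 / 3, scaler = "standard"),
    selection = selection_config("sfs_backward", inner_folds = 3,
                                 max_steps = 2),
    include_behavior = TRUE
  )
}

#' Choose the balanced sensitivity/specificity threshold
#'
#' Scans the midpoints of sorted unique probabilities and returns the
#' threshold minimizing `|TPR - TNR|`; ties are broken by the larger
#' `TPR + TNR`, then by the smaller threshold.  A subject is called a
#' patient when its probability is `>=` the threshold.
#'
#' @param probs Class-1 (schizophrenia) probabilities.
#' @param labels Group labels; both classes must be present.
#' @return The chosen threshold.
#' @export
choose_threshold <- function(probs, labels) {
  y <- labels == "schizophrenia"
  if (!any(y) || all(y)) stop("threshold choice needs both classes")
  u <- sort(unique(probs))
  cand <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else u
  best <- NULL
  for (thr in cand) {
    pred <- probs >= thr
    tpr <- sum(pred & y) / sum(y)
    tnr <- sum(!pred & !y) / sum(!y)
    key <- c(abs(tpr - tnr), -(tpr + tnr), thr)
    if (is.null(best) ||
        key[1] < best[1] - 1e-12 ||
        (abs(key[1] - best[1]) <= 1e-12 && key[2] < best[2] - 1e-12) ||
        (abs(key[1] - best[1]) <= 1e-12 && abs(key[2] - best[2]) <= 1e-12 &&
         key[3] < best[3])) {
      best <- key
    }
  }
  best[3]
}

#' Threshold metrics and confusion counts
#'
#' Sensitivity is the true-positive rate over patients, specificity the
#' true-negative rate over controls, F1 uses the patient class as
#' positive, and AUC is the rank statistic with half credit for ties.
#'
#' @param probs Class-1 probabilities.
#' @param labels Group labels.
#' @param threshold Decision threshold (patient iff `prob >= threshold`).
#' @return List with `sensitivity`, `specificity`, `f1`, `auc`, and
#'   `confusion = c(tp, fp, tn, fn)`.
#' @export
compute_metrics <- function(probs, labels, threshold) {
  stopifnot(is.finite(threshold))
  y <- labels == "schizophrenia"
  pred <- probs >= threshold
  tp <- sum(pred & y)
  fp <- sum(pred & !y)
  tn <- sum(!pred & !y)
  fn <- sum(!pred & y)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
    auc = if (any(y) && any(!y)) rank_auc(probs, labels) else NA_real_,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)
  )
}

#' Fit the full pipeline on a training table
#'
#' Runs selection, fits the model on the retained features, and chooses
#' the decision threshold on out-of-fold predictions from an inner
#' stratified split of the training rows -- the held-out data never enter.
#'
#' @param train_tab Training `feature_table`.
#' @param point A [grid_point()].
#' @param threshold_folds Inner folds for threshold choice (default 5).
#' @param seed Seed for the inner splits.
#' @return Object of class `erp_pipeline` with `selection`, `model`,
#'   `threshold`.
#' @export
fit_pipeline <- function(train_tab, point, threshold_folds = 5, seed = 1) {
  sel <- run_selection(train_tab, point$model, point$selection)
  train_sel <- apply_selection(sel, train_tab)
  model <- fit_model(point$model, train_sel)
  y <- table_groups(train_tab)
  k <- min(threshold_folds, min(table(y)))
  folds <- stratified_folds(y, k, seed)
  oof <- numeric(nrow(train_tab))
  for (f in seq_len(k)) {
    tr <- train_sel[folds != f, , drop = FALSE]
    class(tr) <- c("feature_table", "data.frame")
    m <- fit_model(point$model, tr)
    oof[folds == f] <- predict_proba(m, train_sel[folds == f, , drop = FALSE])
  }
  thr <- choose_threshold(oof, y)
  structure(list(selection = sel, model = model, threshold = thr,
                 point = point),
            class = "erp_pipeline")
}

#' @param pipeline An `erp_pipeline`.
#' @param tab Feature table to score.
#' @rdname fit_pipeline
#' @return `predict_pipeline()`: class-1 probabilities.
#' @export
predict_pipeline <- function(pipeline, tab) {
  predict_proba(pipeline$model, apply_selection(pipeline$selection, tab))
}

#' Cross-validated evaluation of one grid point
#'
#' Extracts features with the point's window parameters, then for each
#' stratified outer fold fits scaler + selection + model on the training
#' rows only, chooses the balanced threshold on training-side out-of-fold
#' predictions, and evaluates on the held-out fold.  Per-fold metrics are
#' aggregated to mean +/- SD; per-fold test confusion counts are summed
#' into one matrix.
#'
#' @param ds An `erp_dataset`.
#' @param point A [grid_point()].
#' @param cv A [cv_config()].
#' @return Object of class `evaluation_report`: `folds` (per-fold
#'   details), `metrics` (mean/sd per metric), `confusion` (summed),
#'   `n_features`, `point`.
#' @export
cross_validate <- function(ds, point, cv = cv_config()) {
  tab <- build_feature_table(ds, point$window_params, point$include_behavior)
  y <- table_groups(tab)
  if (min(table(y)) < cv$outer_folds) {
    stop("outer folds exceed the minority-class count")
  }
  folds <- stratified_folds(y, cv$outer_folds, cv$seed)
  fold_out <- vector("list", cv$outer_folds)
  for (f in seq_len(cv$outer_folds)) {
    tr <- tab[folds != f, , drop = FALSE]
    class(tr) <- c("feature_table", "data.frame")
    te <- tab[folds == f, , drop = FALSE]
    if (nlevels(droplevels(table_groups(te))) < 2L) {
      stop("fold ", f, " has a single class; reduce outer_folds")
    }
    pipe <- fit_pipeline(tr, point, cv$threshold_folds,
                         seed = derive_seed(cv$seed, f))
    p <- predict_pipeline(pipe, te)
    m <- compute_metrics(p, table_groups(te), pipe$threshold)
    sc <- pipe$model$scaler
    fold_out[[f]] <- list(
      metrics = m[c("sensitivity", "specificity", "f1", "auc")],
      confusion = m$confusion, threshold = pipe$threshold,
      kept = pipe$selection$kept,
      scaler_digest = if (is.null(sc$center)) 0 else sum(sc$center) +
        sum(sc$scale),
      model_digest = model_digest(pipe$model))
  }
  metric_names <- c("sensitivity", "specificity", "f1", "auc")
  per_fold <- vapply(fold_out, function(fo) unlist(fo$metrics),
                     numeric(length(metric_names)))
  metrics <- data.frame(
    metric = metric_names,
    mean = rowMeans(per_fold),
    sd = apply(per_fold, 1, stats::sd),
    row.names = NULL)
  confusion <- Reduce(`+`, lapply(fold_out, `[[`, "confusion"))
  structure(
    list(folds = fold_out, metrics = metrics, confusion = confusion,
         per_fold = per_fold, n_features = length(feature_names(tab)),
         point = point, cv = cv),
    class = "evaluation_report"
  )
}

# Scalar fingerprint of fitted estimator parameters, used to verify that
# training-fold fits are unaffected by held-out rows.
model_digest <- function(model) {
  est <- model$estimator
  if (is.null(est)) return(0)
  switch(est$kind,
         logreg = sum(abs(as.numeric(glmnet::coef.glmnet(est$fit)))),
         logreg1 = sum(abs(stats::coef(est$fit))),
         knn = sum(est$x) + as.numeric(est$k),
         svm = sum(abs(est$fit$coefs)) + sum(est$fit$rho) +
           sum(est$platt),
         0)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$cv$outer_folds, "-fold CV, ",
      x$n_features, " features\n", sep = "")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-11s %.3f +/- %.3f\n", m$metric[i], m$mean[i], m$sd[i]))
  }
  cm <- x$confusion
  cat(sprintf("  confusion: tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              cm["tp"], cm["fp"], cm["tn"], cm["fn"], sum(cm)))
  invisible(x)
}

#' Grid search over pipeline configurations
#'
#' Evaluates every grid point with [cross_validate()] and ranks by mean
#' F1, ties broken by mean AUC, then by the smaller retained feature
#' count.  Points that fail (degenerate windows etc.) are recorded and
#' skipped.
#'
#' @param ds An `erp_dataset`.
#' @param grid List of [grid_point()]s (non-empty).
#' @param cv A [cv_config()].
#' @return List with `results` (per-point reports or error messages),
#'   `ranking` (data frame) and `best` (the top report).
#' @export
grid_search <- function(ds, grid, cv = cv_config()) {
  stopifnot(length(grid) >= 1)
  results <- lapply(grid, function(pt) {
    tryCatch(cross_validate(ds, pt, cv), error = function(e) {
      structure(list(message = conditionMessage(e)), class = "grid_failure")
    })
  })
  ok <- !vapply(results, inherits, logical(1), "grid_failure")
  if (!any(ok)) stop("every grid point failed")
  stats_of <- function(r, m) r$metrics$mean[r$metrics$metric == m]
  kept_n <- function(r) {
    ks <- lengths(lapply(r$folds, `[[`, "kept"))
    mean(ks)
  }
  rank_df <- data.frame(
    point = which(ok),
    f1 = vapply(results[ok], stats_of, numeric(1), "f1"),
    auc = vapply(results[ok], stats_of, numeric(1), "auc"),
    n_kept = vapply(results[ok], kept_n, numeric(1)))
  ord <- order(-rank_df$f1, -rank_df$auc, rank_df$n_kept)
  rank_df <- rank_df[ord, , drop = FALSE]
  list(results = results, ranking = rank_df,
       best = results[[rank_df$point[1]]])
}
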