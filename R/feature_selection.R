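# Feature selection: random-probe Shapley filtering, forward/backward
# sequential selection scored by inner cross-validation, and truncated-SVD
# reduction by cumulative explained variance.

#' Selection configuration
#'
#' @param strategy One of `"none"`, `"probe_shap"`, `"sfs_forward"`,
#'   `"sfs_backward"`, `"probe_then_sfs"`, `"truncated_svd"`.
#' @param inner_folds Stratified folds for SFS scoring (default 5, >= 2).
#' @param score_metric Metric comparing feature sets (default `"f1"`;
#'   `"auc"` also supported).
#' @param svd_variance_frac Cumulative explained-variance cutoff in (0, 1\]
#'   for `truncated_svd` (default 0.95).
#' @param probe_seed Seed for the probe column and the Shapley estimator.
#' @param seed Seed for the inner-CV shuffle.
#' @param max_steps Optional budget on accepted SFS steps (default `Inf`);
#'   the stopping rule still applies, the budget only truncates.
#' @param shap_n_perm,shap_n_background,shap_n_rows Budget of the sampling
#'   Shapley estimator used by the probe filter and the SFS tie-break.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(strategy = c("none", "probe_shap",
                                          "sfs_forward", "sfs_backward",
                                          "probe_then_sfs", "truncated_svd"),
                             inner_folds = 5, score_metric = c("f1", "auc"),
                             svd_variance_frac = 0.95, probe_seed = 1,
                             seed = 1, max_steps = Inf, shap_n_perm = 8,
                             shap_n_background = 50, shap_n_rows = 32) {
  stopifnot(inner_folds >= 2,
            svd_variance_frac > 0, svd_variance_frac <= 1)
  structure(
    list(strategy = match.arg(strategy), inner_folds = as.integer(inner_folds),
         score_metric = match.arg(score_metric),
         svd_variance_frac = svd_variance_frac,
         probe_seed = as.integer(probe_seed), seed = as.integer(seed),
         max_steps = max_steps, shap_n_perm = shap_n_perm,
         shap_n_background = shap_n_background, shap_n_rows = shap_n_rows),
    class = "selection_config"
  )
}

selection_result <- function(strategy, kept, trace = NULL,
                             probe_importance = NULL, importance = NULL,
                             projection = NULL, status = "ok") {
  structure(list(strategy = strategy, kept = kept, trace = trace,
                 probe_importance = probe_importance,
                 importance = importance, projection = projection,
                 status = status),
            class = "selection_result")
}

# Mean |Shapley| importance of each feature of a fitted model, using the
# sampling estimator on a row subsample.
shap_importance <- function(model, tab, cfg) {
  n <- nrow(tab)
  rows <- if (n > cfg$shap_n_rows) {
    with_seed(cfg$probe_seed, sample.int(n, cfg$shap_n_rows))
  } else {
    seq_len(n)
  }
  phi <- shap_values(model, tab, rows = rows, estimator = "sampling",
                     n_perm = cfg$shap_n_perm,
                     n_background = cfg$shap_n_background,
                     seed = cfg$probe_seed)
  colMeans(abs(phi))
}

#' Random-probe Shapley filter
#'
#' Appends one standard-normal probe column (drawn with `probe_seed`), fits
#' the model on the augmented table, estimates every feature's global
#' importance as the mean absolute Shapley attribution over a training-row
#' subsample, and keeps the features whose importance strictly exceeds the
#' probe's.  The probe itself is never kept.
#'
#' @param tab A `feature_table` with at least 2 features and both classes.
#' @param spec A [model_spec()].
#' @param cfg A [selection_config()].
#' @return A `selection_result` with `kept`, per-feature `importance` and
#'   `probe_importance`; `status = "all_below_probe"` when nothing
#'   survives.
#' @export
probe_shap_filter <- function(tab, spec, cfg = selection_config("probe_shap")) {
  fn <- feature_names(tab)
  if (length(fn) < 2L) stop("probe filter needs at least 2 features")
  if (nlevels(droplevels(table_groups(tab))) < 2L) {
    stop("probe filter needs both classes")
  }
  probe <- with_seed(cfg$probe_seed, stats::rnorm(nrow(tab)))
  aug <- tab
  aug[["random_probe"]] <- probe
  class(aug) <- c("feature_table", "data.frame")
  model <- fit_model(spec, aug)
  imp <- shap_importance(model, aug, cfg)
  probe_imp <- imp[["random_probe"]]
  kept <- fn[imp[fn] > probe_imp]
  selection_result("probe_shap", kept,
                   probe_importance = probe_imp, importance = imp[fn],
                   status = if (length(kept)) "ok" else "all_below_probe")
}

# Inner-CV score of a candidate feature subset.
score_feature_set <- function(tab, feats, spec, folds, metric) {
  k <- max(folds)
  scores <- numeric(k)
  sub <- subset_features(tab, feats)
  for (f in seq_len(k)) {
    tr <- sub[folds != f, , drop = FALSE]
    class(tr) <- c("feature_table", "data.frame")
    m <- fit_model(spec, tr)
    te <- sub[folds == f, , drop = FALSE]
    p <- predict_proba(m, te)
    y <- table_groups(te)
    scores[f] <- if (metric == "auc") {
      rank_auc(p, y)
    } else {
      pred <- p >= 0.5
      tp <- sum(pred & y == "schizophrenia")
      fp <- sum(pred & y == "healthy")
      fn_ <- sum(!pred & y == "schizophrenia")
      if (2 * tp + fp + fn_ == 0) 0 else 2 * tp / (2 * tp + fp + fn_)
    }
  }
  mean(scores)
}

#' Sequential feature selection on inner cross-validation
#'
#' Backward: starts from all features and repeatedly removes the single
#' feature whose removal yields the highest inner-CV score, as long as the
#' score does not drop below the current one; ties between candidate
#' removals are broken by the smallest mean |Shapley| importance (computed
#' once on the full starting model), then by name.  Forward: starts empty
#' and adds the best-scoring feature while the score strictly improves.
#'
#' @param tab A `feature_table`.
#' @param spec A [model_spec()] whose fits score the candidate sets.
#' @param cfg A [selection_config()]; `cfg$max_steps` bounds the number of
#'   accepted steps.
#' @param direction `"backward"` or `"forward"`.
#' @return A `selection_result` with the retained set and per-step score
#'   trace.
#' @export
sequential_select <- function(tab, spec, cfg = selection_config("sfs_backward"),
                              direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  fn <- feature_names(tab)
  y <- table_groups(tab)
  if (cfg$inner_folds > min(table(y))) {
    stop("inner_folds exceeds the minority-class count")
  }
  folds <- stratified_folds(y, cfg$inner_folds, cfg$seed)
  metric <- cfg$score_metric
  trace <- numeric(0)
  if (direction == "backward") {
    # static tie-break ranking: ascending mean |Shapley| of the full model,
    # estimated with a deliberately small budget (it only orders ties)
    full_model <- fit_model(spec, tab)
    tie_cfg <- cfg
    tie_cfg$shap_n_perm <- 1
    tie_cfg$shap_n_rows <- 8
    tie_cfg$shap_n_background <- 16
    imp <- shap_importance(full_model, tab, tie_cfg)[fn]
    current <- fn
    cur_score <- score_feature_set(tab, current, spec, folds, metric)
    trace <- cur_score
    steps <- 0L
    while (length(current) > 1L && steps < cfg$max_steps) {
      cand_scores <- vapply(current, function(j) {
        score_feature_set(tab, setdiff(current, j), spec, folds, metric)
      }, numeric(1))
      best <- max(cand_scores)
      if (best < cur_score) break
      tied <- current[cand_scores == best]
      drop <- tied[order(imp[tied], tied)][1]
      current <- setdiff(current, drop)
      cur_score <- best
      trace <- c(trace, cur_score)
      steps <- steps + 1L
    }
    selection_result("sfs_backward", current, trace = trace,
                     importance = imp)
  } else {
    current <- character(0)
    cur_score <- 0
    steps <- 0L
    while (length(current) < length(fn) && steps < cfg$max_steps) {
      rest <- setdiff(fn, current)
      cand_scores <- vapply(rest, function(j) {
        score_feature_set(tab, c(current, j), spec, folds, metric)
      }, numeric(1))
      best <- max(cand_scores)
      if (best <= cur_score) break
      tied <- sort(rest[cand_scores == best])
      current <- c(current, tied[1])
      cur_score <- best
      trace <- c(trace, cur_score)
      steps <- steps + 1L
    }
    selection_result("sfs_forward", current, trace = trace)
  }
}

#' Truncated-SVD dimensionality reduction
#'
#' Fits a rank-k linear projection (principal components of the training
#' rows) where k is the smallest component count whose cumulative
#' explained variance reaches `cfg$svd_variance_frac`; the projection is
#' then applied unchanged to held-out rows via [apply_svd()].
#'
#' @param tab Training `feature_table` with at least 2 features.
#' @param cfg A [selection_config()].
#' @return A `selection_result` whose `projection` holds the centering
#'   vector, rotation and k; `kept` names the component columns.
#' @export
svd_reduce <- function(tab, cfg = selection_config("truncated_svd")) {
  fn <- feature_names(tab)
  if (length(fn) < 2L) stop("svd_reduce needs at least 2 features")
  x <- feature_matrix(tab)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- cumsum(ev) / sum(ev)
  k <- which(frac >= cfg$svd_variance_frac - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  proj <- list(center = pc$center, rotation = pc$rotation[, seq_len(k),
                                                          drop = FALSE],
               k = k, explained_frac = frac[k])
  selection_result("truncated_svd", paste0("svd_", seq_len(k)),
                   projection = proj)
}

#' Apply a fitted SVD projection to new rows
#'
#' @param res A `selection_result` from [svd_reduce()].
#' @param tab A `feature_table` with the original feature columns.
#' @return A `feature_table` of component scores `svd_1..svd_k`.
#' @export
apply_svd <- function(res, tab) {
  proj <- res$projection
  x <- as.matrix(tab[, rownames(proj$rotation), drop = FALSE])
  storage.mode(x) <- "double"
  z <- sweep(x, 2, proj$center, "-") %*% proj$rotation
  out <- data.frame(subject_id = tab$subject_id, group = tab$group, z,
                    check.names = FALSE)
  colnames(out) <- c("subject_id", "group", res$kept)
  class(out) <- c("feature_table", "data.frame")
  out
}

# Run the configured selection strategy on a training table; returns a
# selection_result (strategy "none" keeps everything).
run_selection <- function(tab, spec, cfg) {
  switch(cfg$strategy,
         none = selection_result("none", feature_names(tab)),
         probe_shap = probe_shap_filter(tab, spec, cfg),
         sfs_forward = sequential_select(tab, spec, cfg, "forward"),
         sfs_backward = sequential_select(tab, spec, cfg, "backward"),
         probe_then_sfs = {
           first <- probe_shap_filter(tab, spec, cfg)
           if (length(first$kept) < 2L) return(first)
           sub <- subset_features(tab, first$kept)
           out <- sequential_select(sub, spec, cfg, "backward")
           out$strategy <- "probe_then_sfs"
           out$probe_importance <- first$probe_importance
           out
         },
         truncated_svd = svd_reduce(tab, cfg))
}

# Apply a selection result to any table (training or held-out).
apply_selection <- function(res, tab) {
  if (identical(res$strategy, "truncated_svd")) {
    apply_svd(res, tab)
  } else {
    subset_features(tab, res$kept)
  }
}
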