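# Model zoo: penalized logistic regression (glmnet), k-nearest neighbours
# (class::knn), SVM with nonlinear kernels (e1071/libsvm) with Platt
# probability calibration, and the per-paradigm stacking ensemble.  Scaling
# and class-imbalance handling are fitted on the training table only.

#' Specify a classifier
#'
#' @param family `"logreg"`, `"knn"`, `"svm"`, or `"stacking"`.
#' @param penalty `"l1"` or `"l2"` (logreg; SVM is always L2-regularized).
#' @param C Inverse regularization strength, > 0 (logreg / svm cost).
#' @param kernel SVM kernel: `"rbf"`, `"poly"`, or `"sigmoid"`.
#' @param gamma_mode `"scale"` (gamma = 1 / (n_features * var(features)))
#'   or a positive number used directly.
#' @param k Number of neighbours (knn); odd by default.
#' @param imbalance `"class_weight"`, `"weighted_loss"` (both: per-class
#'   weights inversely proportional to class frequency) or `"upsample"`
#'   (seeded minority resampling to majority size).
#' @param scaler `"standard"`, `"minmax"`, `"robust"` or `"none"`.
#' @param seed Seed for the stochastic parts (upsampling).
#' @return Object of class `model_spec`.
#' @export
#' @examples
#' model_spec("svm", C = 1 / 3)           # the best-model SVM
#' model_spec("knn", k = 11)
model_spec <- function(family = c("logreg", "knn", "svm", "stacking"),
                       penalty = c("l2", "l1"), C = 1,
                       kernel = c("rbf", "poly", "sigmoid"),
                       gamma_mode = "scale", k = 11,
                       imbalance = c("class_weight", "weighted_loss",
                                     "upsample"),
                       scaler = c("standard", "minmax", "robust", "none"),
                       seed = 1) {
  family <- match.arg(family)
  stopifnot(C > 0, k >= 1)
  structure(
    list(family = family, penalty = match.arg(penalty), C = C,
         kernel = match.arg(kernel), gamma_mode = gamma_mode,
         k = as.integer(k), imbalance = match.arg(imbalance),
         scaler = match.arg(scaler), seed = as.integer(seed)),
    class = "model_spec"
  )
}

# ---- scalers -----------------------------------------------------------

# Fit scaling statistics on a training matrix.  Zero-spread columns get
# scale 1 so constant features pass through unchanged.
fit_scaler <- function(x, method) {
  method <- match.arg(method, c("standard", "minmax", "robust", "none"))
  center <- scale <- NULL
  if (method == "standard") {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
  } else if (method == "minmax") {
    center <- apply(x, 2, min)
    scale <- apply(x, 2, max) - center
  } else if (method == "robust") {
    center <- apply(x, 2, stats::median)
    scale <- apply(x, 2, function(v) diff(stats::quantile(v, c(0.25, 0.75))))
  }
  if (!is.null(scale)) scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(method = method, center = center, scale = scale),
            class = "erp_scaler")
}

apply_scaler <- function(sc, x) {
  if (sc$method == "none") return(x)
  sweep(sweep(x, 2, sc$center, "-"), 2, sc$scale, "/")
}

# ---- fitting -----------------------------------------------------------

# Inverse-frequency class weights: n / (n_classes * n_class).
balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

upsample_rows <- function(y, seed) {
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  n_extra <- max(tab) - min(tab)
  idx_min <- which(y == minority)
  extra <- with_seed(seed, sample(idx_min, n_extra, replace = TRUE))
  c(seq_along(y), extra)
}

svm_gamma <- function(spec, x) {
  if (identical(spec$gamma_mode, "scale")) {
    v <- stats::var(as.vector(x))
    if (!is.finite(v) || v == 0) v <- 1
    1 / (ncol(x) * v)
  } else {
    as.numeric(spec$gamma_mode)
  }
}

# Platt sigmoid calibration of decision values, fitted on training data.
fit_platt <- function(dv, y01) {
  fit <- suppressWarnings(stats::glm(y01 ~ dv, family = stats::binomial()))
  stats::coef(fit)
}

#' Fit a classifier on a feature table
#'
#' Fits the spec's scaler on this table only, applies the configured
#' imbalance handling, then the estimator.  The schizophrenia group is the
#' positive class.
#'
#' @param spec A [model_spec()] (`family` other than `"stacking"`; see
#'   [fit_stacking()] for the ensemble).
#' @param tab A `feature_table` containing both classes and no missing
#'   values.
#' @return Object of class `fitted_model`.
#' @export
fit_model <- function(spec, tab) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family == "stacking") {
    return(fit_stacking(default_stacking_spec(tab), tab, seed = spec$seed))
  }
  x <- feature_matrix(tab)
  y <- table_groups(tab)
  if (nlevels(droplevels(y)) < 2L) stop("training table has a single class")
  bad <- colnames(x)[apply(x, 2, function(v) any(!is.finite(v)))]
  if (length(bad)) {
    stop("non-finite feature(s): ", paste(bad, collapse = ", "))
  }
  if (spec$imbalance == "upsample") {
    idx <- upsample_rows(y, spec$seed)
    x <- x[idx, , drop = FALSE]
    y <- y[idx]
    cls_w <- c(healthy = 1, schizophrenia = 1)
  } else {
    cls_w <- balanced_weights(y)
  }
  scaler <- fit_scaler(x, spec$scaler)
  xs <- apply_scaler(scaler, x)
  est <- switch(
    spec$family,
    logreg = {
      obs_w <- as.numeric(cls_w[as.character(y)])
      lambda <- 1 / (spec$C * nrow(xs))
      if (ncol(xs) >= 2L) {
        # muffle glmnet's small-class advisory: tiny inner folds are routine
        fit <- withCallingHandlers(
          glmnet::glmnet(xs, y, family = "binomial", weights = obs_w,
                         alpha = if (spec$penalty == "l1") 1 else 0,
                         lambda = lambda, standardize = FALSE,
                         thresh = 1e-12),
          warning = function(w) {
            if (grepl("fewer than 8", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          })
        list(kind = "logreg", fit = fit, lambda = lambda)
      } else {
        # glmnet needs >= 2 predictors; single-feature fits fall back to a
        # weighted unpenalized logistic regression
        df <- data.frame(y01 = as.integer(y == "schizophrenia"), v = xs[, 1])
        fit <- suppressWarnings(
          stats::glm(y01 ~ v, family = stats::binomial(), data = df,
                     weights = obs_w))
        list(kind = "logreg1", fit = fit)
      }
    },
    knn = {
      if (spec$k > nrow(xs)) stop("k exceeds the number of training rows")
      list(kind = "knn", x = xs, y = y, k = spec$k)
    },
    svm = {
      gamma <- svm_gamma(spec, xs)
      kern <- c(rbf = "radial", poly = "polynomial",
                sigmoid = "sigmoid")[[spec$kernel]]
      fit <- e1071::svm(xs, y, kernel = kern, cost = spec$C, gamma = gamma,
                        class.weights = cls_w, scale = FALSE)
      dv <- attr(predict(fit, xs, decision.values = TRUE),
                 "decision.values")[, 1]
      platt <- fit_platt(dv, as.integer(y == "schizophrenia"))
      list(kind = "svm", fit = fit, platt = platt, gamma = gamma)
    }
  )
  structure(
    list(spec = spec, scaler = scaler, feature_names = colnames(x),
         estimator = est, classes = erp_groups()),
    class = "fitted_model"
  )
}

#' Predict class-1 (schizophrenia) probabilities
#'
#' Columns are matched to the training feature names (order-checked);
#' missing columns are an error.  SVM probabilities come from a sigmoid
#' (Platt) calibration of decision values fitted on the training data;
#' kNN probabilities are the unweighted neighbour-vote fraction.
#'
#' @param model A `fitted_model`.
#' @param tab A `feature_table` whose columns cover the training features.
#' @return Numeric vector of probabilities in \[0, 1\], one per row.
#' @export
predict_proba <- function(model, tab) {
  stopifnot(inherits(model, "fitted_model"))
  if (inherits(model, "stacked_model")) return(predict_proba_stack(model, tab))
  miss <- setdiff(model$feature_names, colnames(tab))
  if (length(miss)) {
    stop("prediction table missing feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  }
  x <- as.matrix(tab[, model$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  xs <- apply_scaler(model$scaler, x)
  est <- model$estimator
  p <- switch(
    est$kind,
    logreg = as.numeric(predict(est$fit, xs, type = "response")),
    logreg1 = as.numeric(predict(est$fit, data.frame(v = xs[, 1]),
                                 type = "response")),
    knn = {
      pred <- class::knn(est$x, xs, est$y, k = est$k, prob = TRUE,
                         use.all = TRUE)
      frac <- attr(pred, "prob")
      ifelse(pred == "schizophrenia", frac, 1 - frac)
    },
    svm = {
      dv <- attr(predict(est$fit, xs, decision.values = TRUE),
                 "decision.values")[, 1]
      stats::plogis(est$platt[1] + est$platt[2] * dv)
    }
  )
  clip(as.numeric(p), 0, 1)
}

# ---- stacking ----------------------------------------------------------

#' Specify the per-paradigm stacking ensemble
#'
#' Base learners are logistic regressions, one per feature group (the five
#' condition prefixes plus, optionally, the behavioral columns); the meta
#' learner is an SVM trained on the base class probabilities.
#'
#' @param groups Named list feature-group -> character vector of feature
#'   names; groups must partition the table's feature columns.
#' @param base_spec [model_spec()] for the base logistic regressions.
#' @param meta_spec [model_spec()] for the SVM meta-model.
#' @return Object of class `stacking_spec`.
#' @export
stacking_spec <- function(groups,
                          base_spec = model_spec("logreg", penalty = "l2",
                                                 C = 1),
                          meta_spec = model_spec("svm", C = 1,
                                                 scaler = "none")) {
  if (any(!vapply(groups, length, integer(1)))) {
    empty <- names(groups)[vapply(groups, length, integer(1)) == 0]
    stop("empty stacking group(s): ", paste(empty, collapse = ", "))
  }
  structure(list(groups = groups, base_spec = base_spec,
                 meta_spec = meta_spec),
            class = "stacking_spec")
}

#' Derive the default group partition from a feature table
#'
#' @param tab A `feature_table`.
#' @return A [stacking_spec()] with one group per condition prefix present
#'   plus a `behavior` group when behavioral columns are present.
#' @export
default_stacking_spec <- function(tab) {
  fn <- feature_names(tab)
  beh <- intersect(BEHAVIOR_COLUMNS, fn)
  erp <- setdiff(fn, beh)
  cond <- sub("_.*$", "", erp)
  groups <- split(erp, factor(cond, levels = unique(cond)))
  if (length(beh)) groups$behavior <- beh
  stacking_spec(groups)
}

#' Fit the stacking ensemble
#'
#' Meta-features are out-of-fold base probabilities from a seeded
#' stratified inner cross-validation (one column per base group); the base
#' models are then refitted on all rows for inference and the SVM
#' meta-model is fitted on the meta-feature matrix.
#'
#' @param spec A [stacking_spec()].
#' @param tab A `feature_table`.
#' @param inner_folds Stratified folds for the out-of-fold probabilities
#'   (default 5).
#' @param seed Seed for the fold shuffle.
#' @return A `fitted_model` (subclass `stacked_model`).
#' @export
fit_stacking <- function(spec, tab, inner_folds = 5, seed = 1) {
  stopifnot(inherits(spec, "stacking_spec"))
  fn <- feature_names(tab)
  for (g in names(spec$groups)) {
    miss <- setdiff(spec$groups[[g]], fn)
    if (length(miss)) {
      stop("stacking group '", g, "' names absent feature(s): ",
           paste(miss, collapse = ", "))
    }
  }
  y <- table_groups(tab)
  folds <- stratified_folds(y, inner_folds, seed)
  meta <- matrix(NA_real_, nrow(tab), length(spec$groups),
                 dimnames = list(tab$subject_id, names(spec$groups)))
  for (g in names(spec$groups)) {
    sub <- subset_features(tab, spec$groups[[g]])
    for (f in seq_len(inner_folds)) {
      tr <- sub[folds != f, , drop = FALSE]
      class(tr) <- class(sub)
      m <- fit_model(spec$base_spec, tr)
      meta[folds == f, g] <- predict_proba(m, sub[folds == f, , drop = FALSE])
    }
  }
  base_models <- lapply(spec$groups, function(cols) {
    fit_model(spec$base_spec, subset_features(tab, cols))
  })
  meta_tab <- data.frame(subject_id = tab$subject_id, group = tab$group,
                         meta, check.names = FALSE)
  class(meta_tab) <- c("feature_table", "data.frame")
  meta_model <- fit_model(spec$meta_spec, meta_tab)
  structure(
    list(spec = spec, base_models = base_models, meta_model = meta_model,
         feature_names = fn, classes = erp_groups()),
    class = c("stacked_model", "fitted_model")
  )
}

predict_proba_stack <- function(model, tab) {
  meta <- vapply(names(model$base_models), function(g) {
    predict_proba(model$base_models[[g]],
                  subset_features(tab, model$spec$groups[[g]]))
  }, numeric(nrow(tab)))
  meta <- matrix(meta, nrow = nrow(tab),
                 dimnames = list(NULL, names(model$base_models)))
  meta_tab <- data.frame(subject_id = tab$subject_id, group = tab$group,
                         meta, check.names = FALSE)
  class(meta_tab) <- c("feature_table", "data.frame")
  predict_proba(model$meta_model, meta_tab)
}
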