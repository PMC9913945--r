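# Model interpretation: global mean-|Shapley| feature importance ranking
# and signed per-subject attribution summaries, exported as data so any
# plotting layer can render importance-bar and beeswarm-style views.

#' Global Shapley importance report
#'
#' Computes signed per-subject Shapley attributions (exact enumeration for
#' up to 12 features, permutation sampling above) with a fixed seed and
#' background subsample, and ranks features by mean absolute attribution.
#'
#' @param model A `fitted_model`.
#' @param tab A `feature_table` compatible with the model.
#' @param top_k How many features the ranking reports (clipped to the
#'   feature count, with a warning when larger).
#' @param seed Estimator seed.
#' @param rows Row indices to attribute (default: all rows of `tab`).
#' @param estimator,n_perm,n_background Passed to [shap_values()].
#' @return Object of class `importance_report`: `ranking` (data frame of
#'   feature, mean_abs_shap), `attributions` (subjects x features signed
#'   matrix), `base_value`.
#' @export
global_importance <- function(model, tab, top_k = 15, seed = 1, rows = NULL,
                              estimator = "auto", n_perm = 16,
                              n_background = 100) {
  fn <- model$feature_names
  if (top_k > length(fn)) {
    warning("top_k clipped to the feature count (", length(fn), ")")
    top_k <- length(fn)
  }
  phi <- shap_values(model, tab, rows = rows, estimator = estimator,
                     n_perm = n_perm, n_background = n_background,
                     seed = seed)
  imp <- colMeans(abs(phi))
  ord <- order(-imp)
  ranking <- data.frame(feature = fn[ord], mean_abs_shap = imp[ord],
                        row.names = NULL)
  structure(
    list(ranking = utils::head(ranking, top_k), attributions = phi,
         base_value = attr(phi, "base_value")),
    class = "importance_report"
  )
}

#' Direction of each feature's influence
#'
#' For every attributed feature, the Spearman rank correlation between the
#' feature's values and its signed attributions: positive means larger
#' values push predictions toward the patient class.  Constant features
#' (or constant attributions) get 0 with `degenerate = TRUE`.
#'
#' @param report An `importance_report`.
#' @param tab The `feature_table` the attributions were computed on.
#' @return Data frame with `feature`, `direction`, `degenerate`.
#' @export
direction_summary <- function(report, tab) {
  phi <- report$attributions
  feats <- colnames(phi)
  idx <- match(rownames(phi), tab$subject_id)
  if (anyNA(idx)) stop("attribution rows missing from the feature table")
  vals <- as.matrix(tab[idx, feats, drop = FALSE])
  storage.mode(vals) <- "double"
  out <- lapply(feats, function(j) {
    v <- vals[, j]
    a <- phi[, j]
    if (stats::sd(v) == 0 || stats::sd(a) == 0) {
      data.frame(feature = j, direction = 0, degenerate = TRUE)
    } else {
      data.frame(feature = j,
                 direction = stats::cor(v, a, method = "spearman"),
                 degenerate = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Write an interpretation report to CSV
#'
#' Emits `importance.csv` (feature, mean_abs_shap, direction) and
#' `attributions.csv` (subject x feature signed values) under `dir`.
#'
#' @param report An `importance_report`.
#' @param tab The feature table used for attribution.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_importance_report <- function(report, tab, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dirn <- direction_summary(report, tab)
  imp <- merge(data.frame(feature = colnames(report$attributions),
                          mean_abs_shap = colMeans(abs(report$attributions))),
               dirn, by = "feature")
  imp <- imp[order(-imp$mean_abs_shap), ]
  p1 <- file.path(dir, "importance.csv")
  p2 <- file.path(dir, "attributions.csv")
  data.table::fwrite(imp, p1)
  att <- data.frame(subject_id = rownames(report$attributions),
                    report$attributions, check.names = FALSE)
  data.table::fwrite(att, p2)
  invisible(c(p1, p2))
}
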