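# Config-driven end-to-end pipeline: simulate -> extract -> select/train ->
# evaluate -> interpret, with a resolved-config snapshot written beside the
# outputs so any run can be reproduced from its snapshot alone.  The
# `erpdx` script under inst/exec is a thin command-line front end over
# run_pipeline() and the stage functions.

#' Assemble a run configuration
#'
#' @param out_dir Output directory for reports and snapshots.
#' @param erp_csv,behavior_csv Input paths; omit both to simulate a cohort.
#' @param simulate Logical: generate a synthetic cohort instead of reading
#'   files.
#' @param cohort A [cohort_config()] (used when `simulate`).
#' @param grid List of [grid_point()]s (default: the smoke point).
#' @param cv A [cv_config()].
#' @param interpret_top_k Features in the importance ranking (default 15).
#' @param seed Global seed; stage seeds are derived from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, erp_csv = NULL, behavior_csv = NULL,
                       simulate = is.null(erp_csv),
                       cohort = cohort_config(),
                       grid = list(smoke_grid_point()),
                       cv = cv_config(), interpret_top_k = 15, seed = 1) {
  if (!simulate && is.null(erp_csv)) {
    stop("either provide erp_csv or enable simulate")
  }
  structure(list(out_dir = out_dir, erp_csv = erp_csv,
                 behavior_csv = behavior_csv, simulate = isTRUE(simulate),
                 cohort = cohort, grid = grid, cv = cv,
                 interpret_top_k = interpret_top_k,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Serializable view of the resolved configuration.
config_snapshot <- function(cfg) {
  list(
    seed = cfg$seed, simulate = cfg$simulate,
    erp_csv = cfg$erp_csv, behavior_csv = cfg$behavior_csv,
    cohort = if (cfg$simulate) {
      c <- cfg$cohort
      list(n_healthy = c$n_healthy, n_patient = c$n_patient,
           noise_sd_uv = c$noise_sd_uv, effect_scale = c$effect_scale,
           seed = c$seed, sampling_rate_hz = c$sampling_rate_hz)
    },
    cv = unclass(cfg$cv),
    grid = lapply(cfg$grid, function(pt) {
      list(window_params = lapply(pt$window_params, unclass),
           model = unclass(pt$model), selection = unclass(pt$selection),
           include_behavior = pt$include_behavior)
    })
  )
}

#' Run the full pipeline
#'
#' Stages: simulate (or load) the cohort, extract features per grid point,
#' select/train/evaluate on stratified cross-validation, rank the grid,
#' and interpret the best point's model refitted on the full cohort.
#' Writes `report.json`, `importance.csv`, `attributions.csv`, the feature
#' CSV of the best point, and a `config.json` snapshot under
#' `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @return The [grid_search()] result, invisibly, with an
#'   `importance_report` attached as `$interpretation`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  ds <- if (cfg$simulate) {
    simulate_cohort(cfg$cohort)
  } else {
    d <- load_erp_table(cfg$erp_csv)
    if (!is.null(cfg$behavior_csv)) {
      d <- attach_behavior(d, load_behavior_table(cfg$behavior_csv))
    }
    d
  }
  search <- grid_search(ds, cfg$grid, cfg$cv)
  best <- search$best
  tab <- build_feature_table(ds, best$point$window_params,
                             best$point$include_behavior)
  pipe <- fit_pipeline(tab, best$point, cfg$cv$threshold_folds,
                       seed = derive_seed(cfg$seed, 99))
  sel_tab <- apply_selection(pipe$selection, tab)
  imp <- global_importance(pipe$model, sel_tab, top_k = cfg$interpret_top_k,
                           seed = derive_seed(cfg$seed, 7),
                           estimator = "sampling", n_perm = 8,
                           n_background = 50)
  write_importance_report(imp, sel_tab, cfg$out_dir)
  write_feature_table(tab, file.path(cfg$out_dir, "features.csv"))
  report <- list(
    ranking = search$ranking,
    best = list(
      metrics = best$metrics, confusion = as.list(best$confusion),
      n_features = best$n_features,
      thresholds = vapply(best$folds, `[[`, numeric(1), "threshold"),
      kept = lapply(best$folds, `[[`, "kept")),
    schema_version = 1L)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(config_snapshot(cfg),
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  search$interpretation <- imp
  invisible(search)
}
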