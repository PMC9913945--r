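# Parametrized sliding-window feature extraction: per-window min/max/mean,
# global statistics, extremum-window indices, and the canonical
# `{condition}_{channel}_{type}_{window}` naming template.

#' Window parameters for one condition
#'
#' @param window_size_ms Window size W in milliseconds (> 0).
#' @param shift_pct Shift S between consecutive window starts as a
#'   percentage of the window size, in (0, 100\]; 100 tiles the signal
#'   without overlap.
#' @return Object of class `window_params`.
#' @export
window_params <- function(window_size_ms, shift_pct) {
  stopifnot(window_size_ms > 0, shift_pct > 0, shift_pct <= 100)
  structure(list(window_size_ms = as.numeric(window_size_ms),
                 shift_pct = as.numeric(shift_pct)),
            class = "window_params")
}

#' Default per-condition window parameters
#'
#' The best-model window parameters: plus1 (49 ms, 50 %), plus2 (5 ms,
#' 50 %), nogo (49 ms, 100 %), go (20 ms, 100 %), ph (5 ms, 100 %).
#'
#' @return Named list of [window_params()], class `window_param_set`.
#' @export
default_window_params <- function() {
  structure(list(
    plus1 = window_params(49, 50),
    plus2 = window_params(5, 50),
    nogo  = window_params(49, 100),
    go    = window_params(20, 100),
    ph    = window_params(5, 100)
  ), class = "window_param_set")
}

#' Coarse window parameters for quick runs
#'
#' One window per signal: each condition's window spans its full analysis
#' interval with no overlap, giving the smallest feature table the template
#' admits (8 features per signal).  Used by the smoke grid.
#'
#' @param registry Condition registry.
#' @return A `window_param_set`.
#' @export
coarse_window_params <- function(registry = default_registry()) {
  out <- lapply(registry, function(spec) {
    window_params(spec$interval_end_ms - spec$interval_start_ms, 100)
  })
  structure(out, class = "window_param_set")
}

#' Enumerate sliding windows over a signal
#'
#' With `w = max(1, round(W * fs / 1000))` samples per window and step
#' `s = max(1, round(w * S / 100))`, windows start at `0, s, 2s, ...` while
#' `start + w <= L`; a trailing remainder shorter than `w` is dropped.
#'
#' @param n_samples Signal length L.
#' @param params A [window_params()].
#' @param fs Sampling rate in Hz.
#' @return Integer matrix with columns `start`, `end` (half-open, 0-based),
#'   one row per window; `floor((L - w) / s) + 1` rows.
#' @export
#' @examples
#' nrow(make_windows(50, window_params(49, 50), 250))  # 7 windows
make_windows <- function(n_samples, params, fs) {
  stopifnot(n_samples >= 1)
  w <- max(1L, as.integer(round(params$window_size_ms * fs / 1000)))
  s <- max(1L, as.integer(round(w * params$shift_pct / 100)))
  if (w > n_samples) {
    stop("window of ", w, " samples exceeds signal length ", n_samples)
  }
  starts <- seq.int(0L, n_samples - w, by = s)
  cbind(start = starts, end = starts + w)
}

#' Extract windowed features from one signal
#'
#' Emits, in order: per-window minima `min_1..min_n`, maxima
#' `max_1..max_n`, means `mean_1..mean_n`, then the global `mean`, `max`,
#' `min` over the whole signal, then `argmaxwin` / `argminwin` -- the
#' serial number (1-based) of the first window whose maximum (resp.
#' minimum) equals the global extremum.  Total `3n + 5` values for `n`
#' windows.
#'
#' @param signal Numeric amplitude vector.
#' @param params A [window_params()].
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of feature-name suffixes to values.
#' @export
#' @examples
#' extract_signal_features(c(1, 3, 2, 5, 4), window_params(8, 50), 250)
extract_signal_features <- function(signal, params, fs) {
  win <- make_windows(length(signal), params, fs)
  n <- nrow(win)
  mins <- maxs <- means <- numeric(n)
  for (j in seq_len(n)) {
    seg <- signal[(win[j, "start"] + 1L):win[j, "end"]]
    mins[j] <- min(seg)
    maxs[j] <- max(seg)
    # plain sum/length so the value is bit-identical to a naive reference
    means[j] <- sum(seg) / length(seg)
  }
  gmin <- min(signal)
  gmax <- max(signal)
  argmaxwin <- which(maxs == gmax)[1]
  argminwin <- which(mins == gmin)[1]
  # the global extremum can fall in dropped remainder samples; fall back to
  # the window holding the best windowed value
  if (is.na(argmaxwin)) argmaxwin <- which.max(maxs)
  if (is.na(argminwin)) argminwin <- which.min(mins)
  vals <- c(mins, maxs, means, mean(signal), gmax, gmin, argmaxwin, argminwin)
  names(vals) <- c(paste0("min_", seq_len(n)), paste0("max_", seq_len(n)),
                   paste0("mean_", seq_len(n)),
                   "mean", "max", "min", "argmaxwin", "argminwin")
  vals
}

#' Parse / serialize feature names
#'
#' Feature names follow `{condition}_{channel}_{type}_{window}`, with the
#' window field omitted for global features (`mean`, `max`, `min`,
#' `argmaxwin`, `argminwin`).
#'
#' @param condition,channel,feature_type,window_number Name components;
#'   `window_number = NA` for global features.
#' @return `feature_name()`: the serialized string; `parse_feature_name()`:
#'   a list of components.
#' @export
#' @examples
#' feature_name("plus1", "T6", "min", 1)  # "plus1_T6_min_1"
feature_name <- function(condition, channel, feature_type,
                         window_number = NA) {
  stopifnot(feature_type %in% c("min", "max", "mean", "argmaxwin",
                                "argminwin"))
  if (is.na(window_number)) {
    paste(condition, channel, feature_type, sep = "_")
  } else {
    paste(condition, channel, feature_type, window_number, sep = "_")
  }
}

#' @param x Serialized feature name.
#' @rdname feature_name
#' @export
parse_feature_name <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)[[1]]
  if (length(parts) == 4L) {
    list(condition = parts[1], channel = parts[2], feature_type = parts[3],
         window_number = as.integer(parts[4]))
  } else if (length(parts) == 3L) {
    list(condition = parts[1], channel = parts[2], feature_type = parts[3],
         window_number = NA_integer_)
  } else {
    stop("malformed feature name: ", x)
  }
}

BEHAVIOR_COLUMNS <- c("miss_pct", "false_click_pct", "rt_ms", "rt_var")

#' Build the per-subject feature table
#'
#' Concatenates [extract_signal_features()] over every (condition, channel)
#' of the registry -- registry order, then the condition's channel order --
#' for each subject, optionally followed by the four behavioral columns.
#' Column order is deterministic given (registry, params).
#'
#' @param ds An `erp_dataset`.
#' @param params A `window_param_set` covering every registry condition
#'   (default [default_window_params()]).
#' @param include_behavior Append `miss_pct`, `false_click_pct`, `rt_ms`,
#'   `rt_var` columns (default `FALSE`).
#' @return A `feature_table`: data.frame with `subject_id`, `group`, then
#'   numeric feature columns.
#' @export
build_feature_table <- function(ds, params = default_window_params(),
                                include_behavior = FALSE) {
  stopifnot(inherits(ds, "erp_dataset"))
  miss_p <- setdiff(names(ds$registry), names(params))
  if (length(miss_p)) {
    stop("window parameters missing for condition(s): ",
         paste(miss_p, collapse = ", "))
  }
  fs_of <- function(s, cond, ch) s$erps[[cond]][[ch]]$sampling_rate_hz
  rows <- lapply(ds$subjects, function(s) {
    out <- list()
    for (cond in names(ds$registry)) {
      spec <- ds$registry[[cond]]
      for (ch in spec$channels) {
        w <- s$erps[[cond]][[ch]]
        sig <- slice_interval(w, spec)
        feats <- tryCatch(
          extract_signal_features(sig, params[[cond]], w$sampling_rate_hz),
          error = function(e) {
            stop("feature extraction failed for subject '", s$subject_id,
                 "', condition '", cond, "', channel '", ch, "': ",
                 conditionMessage(e), call. = FALSE)
          })
        names(feats) <- paste(cond, ch, names(feats), sep = "_")
        out[[paste(cond, ch, sep = "_")]] <- feats
      }
    }
    v <- unlist(out, use.names = TRUE)
    names(v) <- sub("^[^.]*\\.", "", names(v))
    if (include_behavior) {
      b <- s$behavior
      if (is.null(b)) {
        stop("subject '", s$subject_id, "' has no behavioral summary")
      }
      v <- c(v, miss_pct = b$miss_pct, false_click_pct = b$false_click_pct,
             rt_ms = b$rt_ms, rt_var = b$rt_var)
    }
    v
  })
  if (length(rows)) {
    mat <- do.call(rbind, rows)
    tab <- data.frame(subject_id = vapply(ds$subjects,
                                          function(s) s$subject_id,
                                          character(1)),
                      group = as.character(group_labels(ds)),
                      mat, check.names = FALSE, row.names = NULL)
  } else {
    # header-only table: derive column names from a probe signal of the
    # right slice length per condition
    cols <- character(0)
    for (cond in names(ds$registry)) {
      spec <- ds$registry[[cond]]
      fs <- 250
      len <- ms_to_sample(spec$interval_end_ms, fs) -
        ms_to_sample(spec$interval_start_ms, fs)
      suff <- names(extract_signal_features(numeric(len) , params[[cond]], fs))
      for (ch in spec$channels) {
        cols <- c(cols, paste(cond, ch, suff, sep = "_"))
      }
    }
    if (include_behavior) cols <- c(cols, BEHAVIOR_COLUMNS)
    tab <- data.frame(matrix(numeric(0), 0, length(cols) + 2,
                             dimnames = list(NULL, c("subject_id", "group",
                                                     cols))),
                      check.names = FALSE)
  }
  if (anyDuplicated(colnames(tab))) stop("duplicated feature names")
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Feature-table accessors
#'
#' @param tab A `feature_table`.
#' @return `feature_names()`: character vector of feature columns;
#'   `feature_matrix()`: the numeric matrix with subject ids as row names;
#'   `table_groups()`: factor of group labels.
#' @export
feature_names <- function(tab) {
  setdiff(colnames(tab), c("subject_id", "group"))
}

#' @rdname feature_names
#' @export
feature_matrix <- function(tab) {
  m <- as.matrix(tab[, feature_names(tab), drop = FALSE])
  rownames(m) <- tab$subject_id
  storage.mode(m) <- "double"
  m
}

#' @rdname feature_names
#' @export
table_groups <- function(tab) factor(tab$group, levels = erp_groups())

# Column subset that preserves the feature_table class and id columns.
subset_features <- function(tab, keep) {
  out <- tab[, c("subject_id", "group", keep), drop = FALSE]
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table CSV
#'
#' @param tab A `feature_table`.
#' @param path CSV path.
#' @return `write_feature_table()`: `path` invisibly;
#'   `load_feature_table()`: a `feature_table`.
#' @export
write_feature_table <- function(tab, path) {
  data.table::fwrite(as.data.frame(tab), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
load_feature_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("subject_id", "group"))))
  class(df) <- c("feature_table", "data.frame")
  df
}
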