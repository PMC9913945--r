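# Domain containers for averaged ERP data: the 10-20 channel set, the
# condition registry (component name -> channels + analysis interval), per
# subject waveform records, and long-format CSV readers/writers.

#' The 19-channel 10--20 montage
#'
#' Electrode labels of the International 10--20 system used throughout the
#' package. Any waveform's channel must be one of these.
#'
#' @return Character vector of 19 electrode labels.
#' @export
#' @examples
#' erp_channels()
erp_channels <- function() {
  c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "C3", "Cz", "C4",
    "T3", "T4", "P3", "Pz", "P4", "T5", "T6", "O1", "O2")
}

#' Group labels
#'
#' The two diagnostic groups: healthy controls and schizophrenia patients.
#' The patient class is the positive class for all metrics.
#'
#' @return Character vector `c("healthy", "schizophrenia")`.
#' @export
erp_groups <- function() c("healthy", "schizophrenia")

#' Define an ERP condition
#'
#' A condition couples a named trial type of the cued Go/NoGo task with the
#' channels and post-stimulus interval over which its ERP component is
#' analyzed.
#'
#' @param name Condition name, one of `"plus1"`, `"plus2"`, `"nogo"`,
#'   `"go"`, `"ph"`.
#' @param channels Character vector of 10--20 electrode labels (non-empty,
#'   duplicate-free subset of [erp_channels()]).
#' @param interval_start_ms,interval_end_ms Analysis interval in
#'   milliseconds relative to the reference stimulus; `start < end`, both
#'   non-negative.
#' @param reference Which stimulus of the pair the interval is locked to:
#'   `"first_stimulus"` or `"second_stimulus"`.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(name, channels, interval_start_ms,
                           interval_end_ms, reference) {
  name <- match.arg(name, c("plus1", "plus2", "nogo", "go", "ph"))
  reference <- match.arg(reference, c("first_stimulus", "second_stimulus"))
  if (length(channels) == 0L) stop("condition '", name, "': empty channel list")
  if (anyDuplicated(channels)) stop("condition '", name, "': duplicated channels")
  bad <- setdiff(channels, erp_channels())
  if (length(bad)) {
    stop("condition '", name, "': unknown channel(s) ",
         paste(bad, collapse = ", "))
  }
  if (!(interval_start_ms >= 0 && interval_end_ms > interval_start_ms)) {
    stop("condition '", name, "': need 0 <= start < end")
  }
  structure(
    list(name = name, channels = as.character(channels),
         interval_start_ms = as.numeric(interval_start_ms),
         interval_end_ms = as.numeric(interval_end_ms),
         reference = reference),
    class = "condition_spec"
  )
}

#' Default condition registry
#'
#' The five analysis conditions with their component intervals and channel
#' sets: `plus1` (P3cue, temporo-occipital, 320--520 ms after the cue),
#' `plus2` (CNV, parietal, 900--1080 ms after the cue), `nogo` (P300 NoGo,
#' centro-parietal, 300--500 ms after the second stimulus), `go` (P3b,
#' centro-parietal, 250--450 ms), and `ph` (P3a, central, 160--220 ms).
#'
#' @return A named list of [condition_spec()] objects, class
#'   `condition_registry`.
#' @export
#' @examples
#' reg <- default_registry()
#' reg$plus2$interval_start_ms
default_registry <- function() {
  specs <- list(
    plus1 = condition_spec("plus1", c("T5", "O1", "O2", "T6"),
                           320, 520, "first_stimulus"),
    plus2 = condition_spec("plus2", c("P3", "Pz", "P4"),
                           900, 1080, "first_stimulus"),
    nogo  = condition_spec("nogo", c("C3", "Cz", "C4", "P3", "Pz", "P4"),
                           300, 500, "second_stimulus"),
    go    = condition_spec("go", c("C3", "Cz", "C4", "P3", "Pz", "P4"),
                           250, 450, "second_stimulus"),
    ph    = condition_spec("ph", c("C3", "Cz", "C4"),
                           160, 220, "second_stimulus")
  )
  structure(specs, class = "condition_registry")
}

#' Build a registry from a plain list
#'
#' Accepts the structure produced by reading a YAML/JSON override file:
#' a mapping `condition -> list(channels, start_ms, end_ms, reference)`.
#'
#' @param x Named list of per-condition entries.
#' @return A `condition_registry`.
#' @export
registry_from_list <- function(x) {
  specs <- lapply(names(x), function(nm) {
    e <- x[[nm]]
    condition_spec(nm, unlist(e$channels), e$start_ms, e$end_ms, e$reference)
  })
  names(specs) <- names(x)
  structure(specs, class = "condition_registry")
}

#' Construct a waveform
#'
#' An averaged ERP trace for one (subject, condition, channel), sampled
#' uniformly.
#'
#' @param samples Numeric amplitude vector in microvolts; non-empty, finite.
#' @param sampling_rate_hz Sampling rate (default 250).
#' @param onset_ms Time of the reference stimulus relative to the first
#'   sample, in ms.  Negative when the trace starts after stimulus onset.
#' @return Object of class `erp_waveform`.
#' @export
waveform <- function(samples, sampling_rate_hz = 250, onset_ms = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("waveform: empty sample vector")
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("waveform: missing or non-finite amplitudes")
  }
  if (!(sampling_rate_hz > 0)) stop("waveform: sampling rate must be positive")
  structure(
    list(samples = samples, sampling_rate_hz = as.numeric(sampling_rate_hz),
         onset_ms = as.numeric(onset_ms)),
    class = "erp_waveform"
  )
}

# Millisecond -> sample-index conversion; round() is IEC half-to-even,
# which keeps interval lengths stable across registry entries.
ms_to_sample <- function(ms, fs) as.integer(round(ms * fs / 1000))

#' Slice a condition's analysis interval out of a waveform
#'
#' Returns the samples of the half-open interval
#' `[interval_start_ms, interval_end_ms)` counted from the reference
#' stimulus: indices `round(start*fs/1000) <= i < round(end*fs/1000)`
#' relative to onset, so the slice length depends only on the interval and
#' the sampling rate (50 samples for 320--520 ms at 250 Hz).
#'
#' @param w An [waveform()].
#' @param spec A [condition_spec()].
#' @return Numeric amplitude vector of length
#'   `round(end*fs/1000) - round(start*fs/1000)`.
#' @export
slice_interval <- function(w, spec) {
  stopifnot(inherits(w, "erp_waveform"), inherits(spec, "condition_spec"))
  fs <- w$sampling_rate_hz
  onset_idx <- ms_to_sample(w$onset_ms, fs)
  i0 <- ms_to_sample(spec$interval_start_ms, fs)
  i1 <- ms_to_sample(spec$interval_end_ms, fs)
  if (i1 <= i0) stop("condition '", spec$name, "': empty interval slice")
  a0 <- onset_idx + i0
  a1 <- onset_idx + i1
  if (a0 < 0L || a1 > length(w$samples)) {
    stop("waveform does not cover ", spec$interval_start_ms, "-",
         spec$interval_end_ms, " ms for condition '", spec$name, "'")
  }
  w$samples[(a0 + 1L):a1]
}

#' Construct a subject record
#'
#' @param subject_id Unique identifier.
#' @param group `"healthy"` or `"schizophrenia"`.
#' @param erps Nested list `erps[[condition]][[channel]]` of [waveform()]s.
#' @param behavior Optional behavioral summary (see [behavior_summary()]).
#' @return Object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group, erps, behavior = NULL) {
  group <- match.arg(group, erp_groups())
  structure(
    list(subject_id = as.character(subject_id), group = group,
         erps = erps, behavior = behavior),
    class = "subject_record"
  )
}

#' Construct an ERP dataset
#'
#' Bundles subject records with the registry that defines which (condition,
#' channel) waveforms they must carry, and validates the coverage invariant:
#' every registry condition has a waveform on each of its channels covering
#' the condition interval.
#'
#' @param subjects List of [subject_record()]s with unique ids.
#' @param registry A `condition_registry` (default [default_registry()]).
#' @param validate Check invariants (default `TRUE`).
#' @return Object of class `erp_dataset`.
#' @export
erp_dataset <- function(subjects, registry = default_registry(),
                        validate = TRUE) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicated subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ds <- structure(list(subjects = subjects, registry = registry),
                  class = "erp_dataset")
  if (validate) validate_erp_dataset(ds)
  ds
}

#' Validate an ERP dataset against its registry
#'
#' @param ds An `erp_dataset`.
#' @return `ds`, invisibly; errors name the offending (subject, condition,
#'   channel) on failure.
#' @export
validate_erp_dataset <- function(ds) {
  stopifnot(inherits(ds, "erp_dataset"))
  for (s in ds$subjects) {
    for (spec in ds$registry) {
      for (ch in spec$channels) {
        w <- s$erps[[spec$name]][[ch]]
        if (is.null(w)) {
          stop("subject '", s$subject_id, "': missing waveform for (",
               spec$name, ", ", ch, ")")
        }
        tryCatch(slice_interval(w, spec), error = function(e) {
          stop("subject '", s$subject_id, "', condition '", spec$name,
               "', channel '", ch, "': ", conditionMessage(e), call. = FALSE)
        })
      }
    }
  }
  invisible(ds)
}

#' @export
print.erp_dataset <- function(x, ...) {
  grp <- table(factor(vapply(x$subjects, function(s) s$group, character(1)),
                      levels = erp_groups()))
  cat("<erp_dataset> ", length(x$subjects), " subjects (",
      grp[["healthy"]], " healthy / ", grp[["schizophrenia"]],
      " schizophrenia), ", length(x$registry), " conditions\n", sep = "")
  invisible(x)
}

group_labels <- function(ds) {
  factor(vapply(ds$subjects, function(s) s$group, character(1)),
         levels = erp_groups())
}

#' Read a long-format ERP table
#'
#' Expects a delimited text file with header columns `subject_id`, `group`,
#' `condition`, `channel`, `time_ms`, `amplitude_uv`; `time_ms` is relative
#' to the condition's reference stimulus.  Waveforms are assembled per
#' (subject, condition, channel) with `time_ms` ascending, and the dataset
#' invariant (interval coverage on every registry channel) is validated.
#'
#' @param path CSV path.
#' @param registry Registry to validate against (default
#'   [default_registry()]).
#' @return An `erp_dataset`.
#' @export
load_erp_table <- function(path, registry = default_registry()) {
  dt <- data.table::fread(path, sep = ",", colClasses = list(
    character = c("subject_id", "group", "condition", "channel")))
  need <- c("subject_id", "group", "condition", "channel", "time_ms",
            "amplitude_uv")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("ERP table '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad_ch <- setdiff(unique(dt$channel), erp_channels())
  if (length(bad_ch)) {
    stop("unknown channel(s): ", paste(bad_ch, collapse = ", "))
  }
  bad_cond <- setdiff(unique(dt$condition), names(registry))
  if (length(bad_cond)) {
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "))
  }
  bad_grp <- setdiff(unique(dt$group), erp_groups())
  if (length(bad_grp)) {
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "))
  }
  data.table::setorder(dt, subject_id, condition, channel, time_ms)
  subjects <- lapply(split(dt, by = "subject_id", sorted = TRUE), function(sd) {
    erps <- list()
    for (piece in split(sd, by = c("condition", "channel"))) {
      t <- piece$time_ms
      if (length(t) < 2L) stop("waveform with fewer than 2 samples")
      step <- diff(t)
      if (max(abs(step - step[1])) > 1e-6) {
        stop("non-uniform sampling for subject '", piece$subject_id[1], "'")
      }
      fs <- 1000 / step[1]
      w <- waveform(piece$amplitude_uv, sampling_rate_hz = fs,
                    onset_ms = -t[1])
      erps[[piece$condition[1]]][[piece$channel[1]]] <- w
    }
    subject_record(sd$subject_id[1], sd$group[1], erps)
  })
  names(subjects) <- NULL
  erp_dataset(subjects, registry)
}

#' Write a long-format ERP table
#'
#' Emits the interchange format read by [load_erp_table()], with amplitudes
#' printed to six decimal places so that a write/load cycle is the identity
#' on the written values.
#'
#' @param ds An `erp_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_erp_table <- function(ds, path) {
  stopifnot(inherits(ds, "erp_dataset"))
  rows <- list()
  for (s in ds$subjects) {
    # canonical order: registry conditions and channel lists first, so a
    # load/write cycle reproduces the file byte for byte
    conds <- c(intersect(names(ds$registry), names(s$erps)),
               setdiff(names(s$erps), names(ds$registry)))
    for (cond in conds) {
      spec_ch <- if (cond %in% names(ds$registry)) {
        ds$registry[[cond]]$channels
      } else {
        character(0)
      }
      chans <- c(intersect(spec_ch, names(s$erps[[cond]])),
                 setdiff(names(s$erps[[cond]]), spec_ch))
      for (ch in chans) {
        w <- s$erps[[cond]][[ch]]
        n <- length(w$samples)
        t <- (seq_len(n) - 1) * 1000 / w$sampling_rate_hz - w$onset_ms
        rows[[length(rows) + 1L]] <- data.table::data.table(
          subject_id = s$subject_id, group = s$group, condition = cond,
          channel = ch, time_ms = t,
          amplitude_uv = as.numeric(sprintf("%.6f", w$samples)))
      }
    }
  }
  if (length(rows)) {
    out <- data.table::rbindlist(rows)
  } else {
    out <- data.table::data.table(
      subject_id = character(), group = character(), condition = character(),
      channel = character(), time_ms = numeric(), amplitude_uv = numeric())
  }
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read / write behavioral summary tables
#'
#' Format: CSV with columns `subject_id`, `group`, `miss_pct`,
#' `false_click_pct`, `rt_ms`, `rt_var`.
#'
#' @param path CSV path.
#' @return `load_behavior_table()`: a data.frame; `write_behavior_table()`:
#'   `path`, invisibly.
#' @export
load_behavior_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("subject_id", "group"))))
  need <- c("subject_id", "group", "miss_pct", "false_click_pct", "rt_ms",
            "rt_var")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("behavior table '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' @param ds An `erp_dataset` whose subjects carry behavior summaries.
#' @rdname load_behavior_table
#' @export
write_behavior_table <- function(ds, path) {
  rows <- lapply(ds$subjects, function(s) {
    b <- s$behavior
    if (is.null(b)) stop("subject '", s$subject_id, "' has no behavior data")
    data.frame(subject_id = s$subject_id, group = s$group,
               miss_pct = b$miss_pct, false_click_pct = b$false_click_pct,
               rt_ms = b$rt_ms, rt_var = b$rt_var)
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Attach behavioral summaries to a dataset
#'
#' @param ds An `erp_dataset`.
#' @param behavior Data frame as returned by [load_behavior_table()].
#' @return The dataset with per-subject `behavior` fields filled in.
#' @export
attach_behavior <- function(ds, behavior) {
  idx <- match(vapply(ds$subjects, function(s) s$subject_id, character(1)),
               behavior$subject_id)
  if (anyNA(idx)) stop("behavior table missing subjects")
  ds$subjects <- Map(function(s, i) {
    s$behavior <- behavior_summary(behavior$miss_pct[i],
                                   behavior$false_click_pct[i],
                                   behavior$rt_ms[i], behavior$rt_var[i])
    s
  }, ds$subjects, idx)
  ds
}
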