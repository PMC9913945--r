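# Seeded synthetic cued Go/NoGo cohorts: Gaussian-bump ERP components with
# group-dependent peak amplitudes (patients attenuated), plus behavioral
# summaries and trial-level responses with the statistical structure the
# downstream analysis assumes.  A waveform model, not a physiological one.

#' Define an ERP component model
#'
#' Each condition's component is a Gaussian bump in time with a per-channel
#' topography weight and group-specific peak amplitude.
#'
#' @param condition Registry condition name.
#' @param latency_ms Bump center, ms post reference stimulus.
#' @param width_ms Gaussian temporal SD, ms (> 0).
#' @param topography Named numeric vector channel -> weight in \[0, 1\];
#'   at least one weight positive.
#' @param amp_healthy_uv,amp_patient_uv Mean peak amplitude magnitudes per
#'   group, microvolts; patients must not exceed healthy (attenuation).
#' @param polarity `+1` or `-1` (CNV is negative).
#' @param subject_sd_frac Between-subject amplitude SD as a fraction of the
#'   group mean.
#' @return Object of class `component_model`.
#' @export
component_model <- function(condition, latency_ms, width_ms, topography,
                            amp_healthy_uv, amp_patient_uv, polarity = 1,
                            subject_sd_frac = 0.25) {
  stopifnot(width_ms > 0, polarity %in% c(-1, 1),
            all(topography >= 0), all(topography <= 1),
            any(topography > 0), subject_sd_frac >= 0)
  if (amp_patient_uv > amp_healthy_uv) {
    stop("component '", condition,
         "': patient amplitude exceeds healthy (no attenuation)")
  }
  structure(
    list(condition = condition, latency_ms = latency_ms, width_ms = width_ms,
         topography = topography, amp_healthy_uv = amp_healthy_uv,
         amp_patient_uv = amp_patient_uv, polarity = polarity,
         subject_sd_frac = subject_sd_frac),
    class = "component_model"
  )
}

#' Default component models
#'
#' One component per registry condition, centered at the midpoint of the
#' condition's analysis interval, supported on the condition's channels:
#' P3cue (plus1, positive), CNV (plus2, negative expectancy wave), P300
#' NoGo, P3b (go) and P3a (ph), all with attenuated patient amplitudes as
#' reported for schizophrenia.
#'
#' @param registry Condition registry (default [default_registry()]).
#' @return Named list of [component_model()]s.
#' @export
#' @examples
#' default_components()$plus1$latency_ms  # 420, midpoint of 320-520 ms
default_components <- function(registry = default_registry()) {
  mid <- function(cond) {
    (registry[[cond]]$interval_start_ms + registry[[cond]]$interval_end_ms) / 2
  }
  comps <- list(
    plus1 = component_model(
      "plus1", mid("plus1"), 40,
      c(T5 = 0.9, O1 = 1, O2 = 1, T6 = 0.9), 8, 5, +1),
    plus2 = component_model(
      "plus2", mid("plus2"), 35,
      c(P3 = 0.9, Pz = 1, P4 = 0.9), 6, 4, -1),
    nogo = component_model(
      "nogo", mid("nogo"), 40,
      c(C3 = 0.8, Cz = 1, C4 = 0.8, P3 = 0.9, Pz = 1, P4 = 0.9), 9, 6, +1),
    go = component_model(
      "go", mid("go"), 40,
      c(C3 = 0.8, Cz = 1, C4 = 0.8, P3 = 0.9, Pz = 1, P4 = 0.9), 8, 5.5, +1),
    ph = component_model(
      "ph", mid("ph"), 15,
      c(C3 = 0.9, Cz = 1, C4 = 0.9), 7, 4.5, +1)
  )
  comps
}

#' Behavioral generating model
#'
#' Group-wise mean and SD for the four behavioral measures.  Defaults are
#' the study-scale group statistics: healthy misses 1.6 +/- 2.8 %, false
#' clicks 0.7 +/- 1.3 %, RT 379 +/- 79 ms, RT variability 8.4 +/- 2.6;
#' patients 9.4 +/- 11.4, 2.0 +/- 6.7, 416 +/- 92, 12.0 +/- 4.8.  Sampled
#' rates are clipped to \[0, 100\] %, RTs to \[200, 1000\] ms.
#'
#' @param healthy,patient Named lists with `mean` and `sd` vectors over
#'   `miss_pct`, `false_click_pct`, `rt_ms`, `rt_var`.
#' @return Object of class `behavior_model`.
#' @export
behavior_model <- function(
    healthy = list(mean = c(miss_pct = 1.6, false_click_pct = 0.7,
                            rt_ms = 379, rt_var = 8.4),
                   sd = c(miss_pct = 2.8, false_click_pct = 1.3,
                          rt_ms = 79, rt_var = 2.6)),
    patient = list(mean = c(miss_pct = 9.4, false_click_pct = 2.0,
                            rt_ms = 416, rt_var = 12.0),
                   sd = c(miss_pct = 11.4, false_click_pct = 6.7,
                          rt_ms = 92, rt_var = 4.8))) {
  stopifnot(all(healthy$sd > 0), all(patient$sd > 0))
  structure(list(healthy = healthy, patient = patient),
            class = "behavior_model")
}

#' Cohort simulation configuration
#'
#' @param n_healthy,n_patient Group sizes (defaults 132 / 68, the study
#'   cohort); at least 2 each.
#' @param noise_sd_uv Additive Gaussian residual noise SD on the averaged
#'   waveforms, microvolts.
#' @param effect_scale Multiplier in \[0, 1\] on the healthy-patient gap,
#'   applied to both the component amplitudes and the behavioral
#'   parameters; 0 yields a null cohort with identical group
#'   distributions.
#' @param seed RNG seed; each subject gets a derived stream so cohorts are
#'   reproducible under subject-count changes.
#' @param sampling_rate_hz Sampling rate (default 250).
#' @param components Component models (default [default_components()]).
#' @param behavior A [behavior_model()].
#' @param registry Condition registry.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_healthy = 132, n_patient = 68, noise_sd_uv = 1.5,
                          effect_scale = 1, seed = 1, sampling_rate_hz = 250,
                          components = default_components(),
                          behavior = behavior_model(),
                          registry = default_registry()) {
  stopifnot(n_healthy >= 2, n_patient >= 2, noise_sd_uv >= 0,
            effect_scale >= 0, effect_scale <= 1, sampling_rate_hz > 0)
  structure(
    list(n_healthy = as.integer(n_healthy), n_patient = as.integer(n_patient),
         noise_sd_uv = noise_sd_uv, effect_scale = effect_scale,
         seed = as.integer(seed), sampling_rate_hz = sampling_rate_hz,
         components = components, behavior = behavior, registry = registry),
    class = "cohort_config"
  )
}

# Sample grid covering a condition's interval plus 100 ms margins, aligned
# so the reference stimulus falls on the grid.
waveform_grid <- function(spec, fs) {
  i0 <- as.integer(floor(max(0, spec$interval_start_ms - 100) * fs / 1000))
  i1 <- as.integer(ceiling((spec$interval_end_ms + 100) * fs / 1000))
  list(start_idx = i0, n = i1 - i0 + 1L, onset_ms = -i0 * 1000 / fs)
}

#' Simulate one subject
#'
#' For each (condition, channel) the waveform is
#' `polarity * A_subj * weight(channel) * exp(-(t - latency)^2 / (2 width^2))`
#' plus i.i.d. Gaussian noise, where `A_subj` is drawn around the group mean
#' amplitude (patient mean pulled toward healthy by `1 - effect_scale`),
#' with SD `subject_sd_frac * mean`, truncated at zero.  Behavioral
#' summaries are drawn from the configured [behavior_model()] with rate and
#' RT clipping.
#'
#' @param group `"healthy"` or `"schizophrenia"`.
#' @param cfg A [cohort_config()].
#' @param subject_id Identifier for the record.
#' @param seed Seed for this subject's stream.
#' @return A [subject_record()].
#' @export
simulate_subject <- function(group, cfg, subject_id = "s1", seed = 1) {
  group <- match.arg(group, erp_groups())
  fs <- cfg$sampling_rate_hz
  with_seed(seed, {
    erps <- list()
    for (cond in names(cfg$registry)) {
      spec <- cfg$registry[[cond]]
      comp <- cfg$components[[cond]]
      if (is.null(comp)) stop("no component model for condition '", cond, "'")
      amp_mean <- if (group == "healthy") {
        comp$amp_healthy_uv
      } else {
        comp$amp_healthy_uv -
          cfg$effect_scale * (comp$amp_healthy_uv - comp$amp_patient_uv)
      }
      a_subj <- max(0, stats::rnorm(1, amp_mean,
                                    comp$subject_sd_frac * amp_mean))
      grid <- waveform_grid(spec, fs)
      t_ms <- (grid$start_idx + seq_len(grid$n) - 1L) * 1000 / fs
      bump <- exp(-(t_ms - comp$latency_ms)^2 / (2 * comp$width_ms^2))
      for (ch in spec$channels) {
        wt <- comp$topography[[ch]] %||% 0
        sig <- comp$polarity * a_subj * wt * bump +
          stats::rnorm(grid$n, 0, cfg$noise_sd_uv)
        erps[[cond]][[ch]] <- waveform(sig, fs, grid$onset_ms)
      }
    }
    # effect_scale interpolates the patient behavioral parameters toward the
    # healthy ones too, so effect_scale = 0 is a true null cohort
    h <- cfg$behavior$healthy
    p <- cfg$behavior$patient
    bm <- if (group == "healthy") {
      h
    } else {
      list(mean = h$mean + cfg$effect_scale * (p$mean - h$mean),
           sd = h$sd + cfg$effect_scale * (p$sd - h$sd))
    }
    draw <- stats::rnorm(4, bm$mean, bm$sd)
    names(draw) <- names(bm$mean)
    beh <- behavior_summary(
      miss_pct = clip(draw[["miss_pct"]], 0, 100),
      false_click_pct = clip(draw[["false_click_pct"]], 0, 100),
      rt_ms = clip(draw[["rt_ms"]], RT_VALID_MIN, RT_VALID_MAX),
      rt_var = max(draw[["rt_var"]], 0.1))
    subject_record(subject_id, group, erps, beh)
  })
}

#' Simulate a full cohort
#'
#' Healthy subjects first (`hc001`, ...), then patients (`sz001`, ...);
#' deterministic for a fixed config.
#'
#' @param cfg A [cohort_config()].
#' @return An `erp_dataset` with behavioral summaries attached.
#' @export
#' @examples
#' ds <- simulate_cohort(cohort_config(n_healthy = 6, n_patient = 4))
#' ds
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  groups <- c(rep("healthy", cfg$n_healthy),
              rep("schizophrenia", cfg$n_patient))
  ids <- c(sprintf("hc%03d", seq_len(cfg$n_healthy)),
           sprintf("sz%03d", seq_len(cfg$n_patient)))
  subjects <- lapply(seq_along(groups), function(i) {
    simulate_subject(groups[i], cfg, ids[i], derive_seed(cfg$seed, i))
  })
  erp_dataset(subjects, cfg$registry)
}

#' Simulate trial-level responses for a subject
#'
#' Go (A-A) trials are missed with probability `miss_pct / 100`, otherwise
#' answered at an RT drawn from the subject's RT distribution (normal with
#' mean `rt_ms` and SD `rt_var/100 * rt_ms`, clipped to the 200--1000 ms
#' validity window); NoGo (A-P) trials are falsely pressed with probability
#' `false_click_pct / 100`.
#'
#' @param subject A [subject_record()] with behavior.
#' @param n_go,n_nogo Trial counts (> 0).
#' @param seed RNG seed.
#' @return List of [trial_response()] objects.
#' @export
simulate_trials <- function(subject, n_go, n_nogo, seed = 1) {
  stopifnot(n_go > 0, n_nogo > 0)
  b <- subject$behavior
  if (is.null(b)) stop("subject has no behavioral summary")
  rt_sd <- b$rt_var / 100 * b$rt_ms
  with_seed(seed, {
    go <- lapply(seq_len(n_go), function(i) {
      if (stats::runif(1) < b$miss_pct / 100) {
        trial_response("AA", FALSE)
      } else {
        trial_response("AA", TRUE,
                       clip(stats::rnorm(1, b$rt_ms, rt_sd),
                            RT_VALID_MIN, RT_VALID_MAX))
      }
    })
    nogo <- lapply(seq_len(n_nogo), function(i) {
      if (stats::runif(1) < b$false_click_pct / 100) {
        trial_response("AP", TRUE,
                       clip(stats::rnorm(1, b$rt_ms, max(rt_sd, 1)),
                            RT_VALID_MIN, RT_VALID_MAX))
      } else {
        trial_response("AP", FALSE)
      }
    })
    c(go, nogo)
  })
}
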