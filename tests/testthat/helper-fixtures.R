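# Fixtures built in code: tiny cohorts, toy feature tables, and the
# brute-force windowed-feature oracle used to check the extractor.

small_cohort <- function(n_healthy = 12, n_patient = 8, seed = 1,
                         effect_scale = 1, ...) {
  simulate_cohort(cohort_config(n_healthy = n_healthy, n_patient = n_patient,
                                seed = seed, effect_scale = effect_scale,
                                ...))
}

# A labelled table of named numeric columns.
toy_table <- function(x, y) {
  tab <- data.frame(subject_id = sprintf("s%03d", seq_along(y)),
                    group = y, x, check.names = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# n subjects, one strong feature (signal) plus pure-noise features.
toy_signal_table <- function(n = 40, n_noise = 5, gap = 3, seed = 1,
                             signal_name = "f1") {
  set.seed(seed)
  y <- rep(c("healthy", "schizophrenia"), each = n / 2)
  x <- matrix(rnorm(n * (n_noise + 1)), n)
  colnames(x) <- c(signal_name,
                   if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  x[, 1] <- x[, 1] + gap * (y == "schizophrenia")
  toy_table(x, y)
}

# Independent oracle for extract_signal_features: naive double loop,
# re-deriving windows and statistics from the definition.
oracle_signal_features <- function(signal, window_size_ms, shift_pct, fs) {
  L <- length(signal)
  w <- max(1, round(window_size_ms * fs / 1000))
  s <- max(1, round(w * shift_pct / 100))
  stopifnot(w <= L)
  starts <- c()
  st <- 0
  while (st + w <= L) {
    starts <- c(starts, st)
    st <- st + s
  }
  mins <- maxs <- means <- c()
  for (st in starts) {
    seg <- c()
    for (i in seq_len(w)) seg <- c(seg, signal[st + i])
    mins <- c(mins, min(seg))
    maxs <- c(maxs, max(seg))
    means <- c(means, sum(seg) / w)
  }
  gmax <- max(signal)
  gmin <- min(signal)
  amax <- NA
  amin <- NA
  for (j in seq_along(starts)) {
    if (is.na(amax) && maxs[j] == gmax) amax <- j
    if (is.na(amin) && mins[j] == gmin) amin <- j
  }
  if (is.na(amax)) amax <- which.max(maxs)
  if (is.na(amin)) amin <- which.min(mins)
  c(mins, maxs, means, mean(signal), gmax, gmin, amax, amin)
}

# Replace every ERP amplitude of the given subjects with pure noise.
scramble_subjects <- function(ds, ids, seed = 99) {
  set.seed(seed)
  ds$subjects <- lapply(ds$subjects, function(s) {
    if (!(s$subject_id %in% ids)) return(s)
    for (cond in names(s$erps)) {
      for (ch in names(s$erps[[cond]])) {
        w <- s$erps[[cond]][[ch]]
        w$samples <- rnorm(length(w$samples), 0, 5)
        s$erps[[cond]][[ch]] <- w
      }
    }
    s
  })
  ds
}
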