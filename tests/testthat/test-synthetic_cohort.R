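test_that("default components sit at interval midpoints with stated polarity", {
  comps <- default_components()
  expect_equal(comps$plus1$latency_ms, 420)
  expect_equal(comps$plus2$latency_ms, 990)
  expect_equal(comps$ph$latency_ms, 190)
  expect_equal(comps$plus2$polarity, -1)  # CNV is a negative expectancy wave
  for (cm in comps) {
    expect_lte(cm$amp_patient_uv, cm$amp_healthy_uv)
    expect_true(all(cm$topography >= 0 & cm$topography <= 1))
  }
  expect_error(component_model("plus1", 420, 40, c(T5 = 1), 5, 8),
               "attenuation")
})

test_that("noise-free subjects hit the configured peak amplitude exactly", {
  cfg <- cohort_config(n_healthy = 2, n_patient = 2, noise_sd_uv = 0)
  cfg$components <- lapply(cfg$components, function(cm) {
    cm$subject_sd_frac <- 0
    cm
  })
  s <- simulate_subject("healthy", cfg, "h1", seed = 5)
  # plus1 latency (420 ms) falls on the sample grid: peak is exact
  w <- s$erps$plus1$O1
  expect_equal(max(w$samples), cfg$components$plus1$amp_healthy_uv *
                 cfg$components$plus1$topography[["O1"]])
  p <- simulate_subject("schizophrenia", cfg, "p1", seed = 5)
  expect_equal(max(p$erps$plus1$O1$samples),
               cfg$components$plus1$amp_patient_uv)
  # CNV bump is negative
  expect_lt(min(p$erps$plus2$Pz$samples), 0)
  expect_error(simulate_subject("other", cfg), "arg")
})

test_that("a null cohort draws patients from the healthy distributions", {
  cfg <- cohort_config(n_healthy = 2, n_patient = 2, noise_sd_uv = 0,
                       effect_scale = 0)
  cfg$components <- lapply(cfg$components, function(cm) {
    cm$subject_sd_frac <- 0
    cm
  })
  h <- simulate_subject("healthy", cfg, "x", seed = 7)
  p <- simulate_subject("schizophrenia", cfg, "x", seed = 7)
  for (cond in names(h$erps)) {
    for (ch in names(h$erps[[cond]])) {
      expect_equal(p$erps[[cond]][[ch]]$samples, h$erps[[cond]][[ch]]$samples)
    }
  }
  expect_equal(unlist(p$behavior), unlist(h$behavior))
})

test_that("cohorts are deterministic per seed and differ across seeds", {
  a <- small_cohort(4, 3, seed = 11)
  b <- small_cohort(4, 3, seed = 11)
  expect_identical(a, b)
  c <- small_cohort(4, 3, seed = 12)
  expect_false(identical(a$subjects[[1]]$erps$plus1$T5$samples,
                         c$subjects[[1]]$erps$plus1$T5$samples))
  expect_equal(length(a$subjects), 7)
  expect_equal(sum(group_labels <- vapply(a$subjects, function(s) s$group,
                                          character(1)) == "healthy"), 4)
  # subject ids encode group and index
  expect_equal(a$subjects[[1]]$subject_id, "hc001")
  expect_equal(a$subjects[[5]]$subject_id, "sz001")
})

test_that("default cohort counts are 132 healthy / 68 patients", {
  cfg <- cohort_config()
  expect_equal(cfg$n_healthy, 132L)
  expect_equal(cfg$n_patient, 68L)
})

test_that("patient peak amplitudes concentrate on the configured mean", {
  cfg <- cohort_config(n_healthy = 2, n_patient = 2, noise_sd_uv = 0)
  comp <- cfg$components$plus1
  n <- 600
  peaks <- vapply(seq_len(n), function(i) {
    s <- simulate_subject("schizophrenia", cfg, "p", seed = 1000 + i)
    max(s$erps$plus1$O1$samples)
  }, numeric(1))
  se <- comp$subject_sd_frac * comp$amp_patient_uv / sqrt(n)
  expect_lt(abs(mean(peaks) - comp$amp_patient_uv), 3 * se)
})

test_that("grand-average group difference has the configured sign", {
  ds <- simulate_cohort(cohort_config(n_healthy = 40, n_patient = 30,
                                      seed = 3))
  grp <- vapply(ds$subjects, function(s) s$group, character(1))
  comps <- default_components()
  for (cond in names(ds$registry)) {
    comp <- comps[[cond]]
    for (ch in names(comp$topography)) {
      if (comp$topography[[ch]] == 0) next
      lat_val <- vapply(ds$subjects, function(s) {
        w <- s$erps[[cond]][[ch]]
        t_ms <- (seq_along(w$samples) - 1) * 1000 / w$sampling_rate_hz -
          w$onset_ms
        w$samples[which.min(abs(t_ms - comp$latency_ms))]
      }, numeric(1))
      d <- mean(lat_val[grp == "healthy"]) -
        mean(lat_val[grp == "schizophrenia"])
      expect_gt(d * comp$polarity, 0)
    }
  }
})

test_that("behavior draws match the generating model within 3 SE", {
  cfg <- cohort_config()
  n <- 2000
  h <- vapply(seq_len(n), function(i) {
    s <- simulate_subject("healthy", cfg, "h", seed = 20000 + i)
    c(s$behavior$rt_ms, s$behavior$rt_var, s$behavior$miss_pct)
  }, numeric(3))
  bm <- cfg$behavior$healthy
  expect_lt(abs(mean(h[1, ]) - bm$mean[["rt_ms"]]),
            3 * bm$sd[["rt_ms"]] / sqrt(n) + 1)  # +1 ms clip allowance
  expect_lt(abs(mean(h[2, ]) - bm$mean[["rt_var"]]),
            3 * bm$sd[["rt_var"]] / sqrt(n) + 0.05)
  # rates are clipped at 0, so compare against the clipped-normal mean
  mu <- bm$mean[["miss_pct"]]
  sg <- bm$sd[["miss_pct"]]
  clip_mean <- mu * pnorm(mu / sg) + sg * dnorm(mu / sg)
  expect_lt(abs(mean(h[3, ]) - clip_mean), 3 * sg / sqrt(n))
})

test_that("simulated trials reproduce the subject's behavior summary", {
  ds <- small_cohort(2, 2, seed = 9)
  s <- ds$subjects[[4]]
  tr <- simulate_trials(s, n_go = 8000, n_nogo = 8000, seed = 13)
  expect_length(tr, 16000)
  b <- summarize_behavior(tr)
  p_miss <- s$behavior$miss_pct / 100
  se_miss <- sqrt(p_miss * (1 - p_miss) / 8000)
  expect_lt(abs(b$miss_pct / 100 - p_miss), 3 * se_miss + 1e-9)
  p_fc <- s$behavior$false_click_pct / 100
  se_fc <- sqrt(p_fc * (1 - p_fc) / 8000)
  expect_lt(abs(b$false_click_pct / 100 - p_fc), 3 * se_fc + 1e-9)
  # degenerate rates
  s$behavior$miss_pct <- 0
  tr0 <- simulate_trials(s, 200, 10, seed = 1)
  aa <- Filter(function(t) t$trial_type == "AA", tr0)
  expect_true(all(vapply(aa, function(t) t$pressed, logical(1))))
  s$behavior$miss_pct <- 100
  tr1 <- simulate_trials(s, 200, 10, seed = 1)
  aa1 <- Filter(function(t) t$trial_type == "AA", tr1)
  expect_false(any(vapply(aa1, function(t) t$pressed, logical(1))))
})
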