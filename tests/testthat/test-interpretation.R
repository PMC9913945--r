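test_that("attributions satisfy null-player, symmetry, and additivity", {
  set.seed(3)
  n <- 30
  x <- cbind(f_a = rnorm(n), f_b = rnorm(n), f_const = rep(1, n))
  x <- cbind(x, f_dup = x[, "f_a"])
  y <- ifelse(x[, "f_a"] + x[, "f_dup"] + 0.5 * x[, "f_b"] +
                rnorm(n, 0, 0.3) > 0, "schizophrenia", "healthy")
  tab <- toy_table(x, y)
  m <- fit_model(model_spec("logreg", penalty = "l2", C = 10,
                            scaler = "none"), tab)
  # make the fitted linear model exactly symmetric in the duplicated pair
  # (the solver itself equalizes the two coefficients only to ~1e-7)
  b <- m$estimator$fit$beta
  b[c("f_a", "f_dup"), 1] <- mean(b[c("f_a", "f_dup"), 1])
  m$estimator$fit$beta <- b
  phi <- shap_values(m, tab, estimator = "exact", seed = 2)
  # null player: the constant feature changes no coalition value
  expect_lt(max(abs(phi[, "f_const"])), 1e-10)
  # symmetry: identical columns receive identical attributions
  expect_equal(phi[, "f_a"], phi[, "f_dup"], tolerance = 1e-10)
  # additivity: rows sum to prediction minus base value
  p <- predict_proba(m, tab)
  expect_equal(unname(rowSums(phi)), p - attr(phi, "base_value"),
               tolerance = 1e-10)
  # the sampling estimator telescopes, so additivity is exact there too
  phi_s <- shap_values(m, tab, estimator = "sampling", n_perm = 4, seed = 2)
  expect_equal(unname(rowSums(phi_s)), p - attr(phi_s, "base_value"),
               tolerance = 1e-10)
  expect_lt(max(abs(phi_s[, "f_const"])), 1e-10)
})

test_that("sampling estimator converges to the exact values", {
  set.seed(5)
  n <- 25
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- ifelse(x[, "a"] - x[, "b"] > 0, "schizophrenia", "healthy")
  tab <- toy_table(x, y)
  m <- fit_model(model_spec("logreg", C = 10, scaler = "none"), tab)
  exact <- shap_values(m, tab, estimator = "exact", seed = 4)
  approx <- shap_values(m, tab, estimator = "sampling", n_perm = 200,
                        seed = 4)
  expect_lt(max(abs(exact - approx)), 0.05)
})

test_that("global_importance ranks by mean absolute attribution", {
  tab <- toy_signal_table(n = 30, n_noise = 3, gap = 6, seed = 11)
  m <- fit_model(model_spec("logreg", C = 1), tab)
  rep <- global_importance(m, tab, top_k = 2, seed = 1)
  expect_equal(rep$ranking$feature[1], "f1")
  expect_equal(nrow(rep$ranking), 2)
  expect_true(all(diff(rep$ranking$mean_abs_shap) <= 0))
  expect_equal(dim(rep$attributions), c(30, 4))
  expect_warning(global_importance(m, tab, top_k = 99, seed = 1), "clipped")
})

test_that("direction_summary signs follow the model output", {
  set.seed(13)
  n <- 40
  x <- cbind(up = rnorm(n), flat = rep(1, n))
  y <- ifelse(x[, "up"] + rnorm(n, 0, 0.2) > 0, "schizophrenia", "healthy")
  tab <- toy_table(x, y)
  m <- fit_model(model_spec("logreg", C = 10, scaler = "none"), tab)
  rep <- global_importance(m, tab, top_k = 2, seed = 1, estimator = "exact")
  d <- direction_summary(rep, tab)
  # the model output is monotone in the single live feature, so the signed
  # attribution is a monotone function of its value: rank correlation +1
  expect_equal(d$direction[d$feature == "up"], 1)
  expect_equal(d$direction[d$feature == "flat"], 0)
  expect_true(d$degenerate[d$feature == "flat"])
  # negated copy of the output: correlation -1
  x2 <- cbind(down = -x[, "up"], flat = rep(1, n))
  tab2 <- toy_table(x2, y)
  m2 <- fit_model(model_spec("logreg", C = 10, scaler = "none"), tab2)
  rep2 <- global_importance(m2, tab2, top_k = 2, seed = 1,
                            estimator = "exact")
  d2 <- direction_summary(rep2, tab2)
  expect_equal(d2$direction[d2$feature == "down"], -1)
})

test_that("a misses-only signal puts miss_pct at the top of the ranking", {
  # null ERPs and a behavior model whose groups differ in misses only
  bm <- behavior_model()
  bm$patient$mean[c("false_click_pct", "rt_ms", "rt_var")] <-
    bm$healthy$mean[c("false_click_pct", "rt_ms", "rt_var")]
  bm$patient$sd[c("false_click_pct", "rt_ms", "rt_var")] <-
    bm$healthy$sd[c("false_click_pct", "rt_ms", "rt_var")]
  bm$patient$mean["miss_pct"] <- 40
  bm$patient$sd["miss_pct"] <- 8
  cfg <- cohort_config(n_healthy = 40, n_patient = 30, seed = 19,
                       behavior = bm)
  cfg$components <- lapply(cfg$components, function(cm) {
    cm$amp_patient_uv <- cm$amp_healthy_uv  # no ERP group difference
    cm
  })
  ds <- simulate_cohort(cfg)
  tab <- build_feature_table(ds, coarse_window_params(), TRUE)
  m <- fit_model(model_spec("logreg", C = 1), tab)
  rep <- global_importance(m, tab, top_k = 5, seed = 3,
                           estimator = "sampling", n_perm = 8,
                           n_background = 40)
  expect_equal(rep$ranking$feature[1], "miss_pct")
  d <- direction_summary(rep, tab)
  expect_gt(d$direction[d$feature == "miss_pct"], 0)
})

test_that("top-ranked features are stable across estimator seeds", {
  tab <- toy_signal_table(n = 60, n_noise = 12, gap = 4, seed = 23)
  tab$f2 <- tab$f1 + rnorm(60, 0, 0.5)
  class(tab) <- c("feature_table", "data.frame")
  m <- fit_model(model_spec("logreg", C = 1), tab)
  tops <- lapply(1:10, function(s) {
    r <- global_importance(m, tab, top_k = 2, seed = s,
                           estimator = "sampling", n_perm = 8)
    sort(r$ranking$feature)
  })
  ref <- tops[[1]]
  expect_gte(sum(vapply(tops, identical, logical(1), ref)), 9)
})

test_that("importance reports are written as CSV data", {
  tab <- toy_signal_table(n = 20, n_noise = 2, seed = 29)
  m <- fit_model(model_spec("logreg", C = 1), tab)
  rep <- global_importance(m, tab, top_k = 3, seed = 1)
  dir <- tempfile()
  paths <- write_importance_report(rep, tab, dir)
  expect_true(all(file.exists(file.path(dir, c("importance.csv",
                                               "attributions.csv")))))
  imp <- utils::read.csv(file.path(dir, "importance.csv"))
  expect_equal(sort(imp$feature), sort(feature_names(tab)))
})
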