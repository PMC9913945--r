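# Behavioral summaries from trial-level responses, and the one-way
# two-level ANOVA used for the group comparison of the behavioral table.

#' Behavioral summary of one subject
#'
#' @param miss_pct Percentage of Go (A-A) trials without a valid press.
#' @param false_click_pct Percentage of NoGo (A-P) trials with a press.
#' @param rt_ms Mean reaction time over valid Go presses, ms.
#' @param rt_var Reaction-time dispersion index: the coefficient of
#'   variation in percent, `100 * sd(rt) / mean(rt)`.
#' @return Object of class `behavior_summary`.
#' @export
behavior_summary <- function(miss_pct, false_click_pct, rt_ms, rt_var) {
  stopifnot(miss_pct >= 0, miss_pct <= 100,
            false_click_pct >= 0, false_click_pct <= 100)
  structure(list(miss_pct = as.numeric(miss_pct),
                 false_click_pct = as.numeric(false_click_pct),
                 rt_ms = as.numeric(rt_ms), rt_var = as.numeric(rt_var)),
            class = "behavior_summary")
}

#' A trial-level response record
#'
#' @param trial_type One of `"AA"`, `"AP"`, `"PP"`, `"PH"`.
#' @param pressed Logical: was the button pressed.
#' @param rt_ms Response latency in ms; required iff `pressed`.
#' @return Object of class `trial_response`.
#' @export
trial_response <- function(trial_type, pressed, rt_ms = NA_real_) {
  trial_type <- match.arg(trial_type, c("AA", "AP", "PP", "PH"))
  if (pressed && is.na(rt_ms)) stop("pressed trial needs rt_ms")
  if (!pressed && !is.na(rt_ms)) stop("rt_ms given for a non-press trial")
  structure(list(trial_type = trial_type, pressed = isTRUE(pressed),
                 rt_ms = as.numeric(rt_ms)),
            class = "trial_response")
}

# Response-validity window, ms after the target stimulus.
RT_VALID_MIN <- 200
RT_VALID_MAX <- 1000

#' Summarize trial-level responses
#'
#' A press counts as valid only within the 200--1000 ms window after the
#' target stimulus; presses outside it count as misses. Misses are the
#' fraction of A-A (Go) trials without a valid press; false clicks the
#' fraction of A-P (NoGo) trials with any press. RT statistics cover valid
#' Go presses only, with `rt_var` the coefficient of variation in percent.
#'
#' @param trials List of [trial_response()] objects; must contain at least
#'   one AA trial.
#' @return A [behavior_summary()].
#' @export
summarize_behavior <- function(trials) {
  type <- vapply(trials, function(t) t$trial_type, character(1))
  pressed <- vapply(trials, function(t) t$pressed, logical(1))
  rt <- vapply(trials, function(t) t$rt_ms, numeric(1))
  aa <- type == "AA"
  ap <- type == "AP"
  if (!any(aa)) stop("no A-A (Go) trials to summarize")
  valid <- pressed & !is.na(rt) & rt >= RT_VALID_MIN & rt <= RT_VALID_MAX
  miss_pct <- 100 * sum(aa & !valid) / sum(aa)
  false_click_pct <- if (any(ap)) 100 * sum(ap & pressed) / sum(ap) else 0
  rts <- rt[aa & valid]
  if (length(rts)) {
    m <- mean(rts)
    v <- if (length(rts) > 1L) 100 * stats::sd(rts) / m else 0
  } else {
    m <- NA_real_
    v <- NA_real_
  }
  behavior_summary(miss_pct, false_click_pct,
                   rt_ms = if (is.na(m)) 0 else m,
                   rt_var = if (is.na(v)) 0 else v)
}

#' One-way two-level ANOVA
#'
#' Classical one-way analysis of variance for a factor with two levels:
#' `F = MS_between / MS_within` on `(1, nA + nB - 2)` degrees of freedom.
#' Identical (to rounding) to the squared pooled-variance two-sample t
#' statistic.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 values.
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' anova_two_level(c(1, 2, 3), c(2, 3, 4))  # F = 1.5 on (1, 4)
anova_two_level <- function(values_a, values_b) {
  na <- length(values_a)
  nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  anova_from_summary(na, mean(values_a), stats::sd(values_a),
                     nb, mean(values_b), stats::sd(values_b))
}

#' @param n_a,n_b Group sizes.
#' @param mean_a,mean_b Group means.
#' @param sd_a,sd_b Group standard deviations (denominator n - 1).
#' @rdname anova_two_level
#' @export
#' @examples
#' # group-size / mean / SD form: misses of 132 controls vs 68 patients
#' anova_from_summary(132, 1.6, 2.8, 68, 9.4, 11.4)$f
anova_from_summary <- function(n_a, mean_a, sd_a, n_b, mean_b, sd_b) {
  n <- n_a + n_b
  gm <- (n_a * mean_a + n_b * mean_b) / n
  ssb <- n_a * (mean_a - gm)^2 + n_b * (mean_b - gm)^2
  ssw <- (n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2
  df2 <- n - 2
  if (ssw <= 0) stop("zero pooled within-group variance")
  f <- ssb / (ssw / df2)
  list(f = f, df1 = 1L, df2 = as.integer(df2),
       p = stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Group comparison table for behavioral measures
#'
#' Computes per-group mean and SD plus the one-way ANOVA F and p for each
#' behavioral measure of a cohort.
#'
#' @param behavior Data frame with `group` and the four behavioral columns.
#' @return Data frame, one row per measure.
#' @export
behavior_group_table <- function(behavior) {
  measures <- c("miss_pct", "false_click_pct", "rt_ms", "rt_var")
  h <- behavior[behavior$group == "healthy", , drop = FALSE]
  p <- behavior[behavior$group == "schizophrenia", , drop = FALSE]
  do.call(rbind, lapply(measures, function(m) {
    a <- anova_two_level(h[[m]], p[[m]])
    data.frame(measure = m,
               healthy_mean = mean(h[[m]]), healthy_sd = stats::sd(h[[m]]),
               patient_mean = mean(p[[m]]), patient_sd = stats::sd(p[[m]]),
               f = a$f, p = a$p)
  }))
}
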