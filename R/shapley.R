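# Model-agnostic Shapley attributions with a background-sample value
# function: an exact subset-enumeration estimator for small feature counts
# and a permutation-sampling estimator for larger ones.  The value of a
# coalition S at row x is the mean model output over background rows with
# the S columns replaced by x's values, so attributions for one row sum to
# f(x) minus the mean background output (additivity), exactly for both
# estimators (per-permutation telescoping).

# Predict probabilities for a bare numeric matrix with the model's feature
# columns.
predict_matrix <- function(model, x) {
  tab <- data.frame(subject_id = sprintf("r%d", seq_len(nrow(x))),
                    group = "healthy", x, check.names = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  predict_proba(model, tab)
}

#' Shapley attributions for a fitted model
#'
#' @param model A `fitted_model`.
#' @param tab `feature_table` providing the rows to explain.
#' @param rows Row indices of `tab` to explain (default: all).
#' @param background Matrix of background rows (default: up to
#'   `n_background` rows of `tab`, sampled with `seed`).
#' @param estimator `"exact"` (subset enumeration, feasible for up to ~12
#'   features), `"sampling"` (permutation sampling), or `"auto"`.
#' @param n_perm Permutations per row for the sampling estimator.
#' @param n_background Background subsample size (default 100).
#' @param seed Seed for background subsampling and permutations.
#' @return Numeric matrix (explained rows x features) of signed
#'   attributions, with attribute `base_value` (mean background output).
#' @export
shap_values <- function(model, tab, rows = NULL, background = NULL,
                        estimator = c("auto", "exact", "sampling"),
                        n_perm = 16, n_background = 100, seed = 1) {
  estimator <- match.arg(estimator)
  fn <- model$feature_names
  x_all <- as.matrix(tab[, fn, drop = FALSE])
  storage.mode(x_all) <- "double"
  if (is.null(rows)) rows <- seq_len(nrow(x_all))
  if (is.null(background)) {
    nb <- min(n_background, nrow(x_all))
    bi <- with_seed(seed, sample.int(nrow(x_all), nb))
    background <- x_all[bi, , drop = FALSE]
  }
  d <- length(fn)
  if (estimator == "auto") {
    estimator <- if (d <= 12) "exact" else "sampling"
  }
  x_expl <- x_all[rows, , drop = FALSE]
  phi <- if (estimator == "exact") {
    shap_exact(model, x_expl, background)
  } else {
    shap_sampling(model, x_expl, background, n_perm, seed)
  }
  dimnames(phi) <- list(tab$subject_id[rows], fn)
  attr(phi, "base_value") <- mean(predict_matrix(model, background))
  phi
}

# Exact Shapley values by subset enumeration (2^d coalitions).
shap_exact <- function(model, x_expl, background) {
  d <- ncol(x_expl)
  if (d > 14) stop("exact estimator limited to 14 features")
  n_e <- nrow(x_expl)
  n_b <- nrow(background)
  n_sub <- bitwShiftL(1L, d)
  # v[s, e]: value of coalition with bitmask s-1 for explained row e
  v <- matrix(NA_real_, n_sub, n_e)
  for (s in seq_len(n_sub)) {
    mask <- bitwAnd(bitwShiftR(s - 1L, 0:(d - 1L)), 1L) == 1L
    big <- background[rep(seq_len(n_b), n_e), , drop = FALSE]
    if (any(mask)) {
      repl <- x_expl[rep(seq_len(n_e), each = n_b), mask, drop = FALSE]
      big[, mask] <- repl
    }
    p <- predict_matrix(model, big)
    v[s, ] <- colMeans(matrix(p, n_b, n_e))
  }
  fact <- factorial(0:d)
  phi <- matrix(0, n_e, d)
  for (s in seq_len(n_sub)) {
    bits <- bitwAnd(bitwShiftR(s - 1L, 0:(d - 1L)), 1L) == 1L
    k <- sum(bits)
    if (k == d) next
    w <- fact[k + 1] * fact[d - k] / fact[d + 1]
    for (j in which(!bits)) {
      s_with <- s + bitwShiftL(1L, j - 1L)
      phi[, j] <- phi[, j] + w * (v[s_with, ] - v[s, ])
    }
  }
  phi
}

# Permutation-sampling Shapley values: for each explained row and sampled
# permutation, features are switched from background to the row's values
# one at a time; marginal value changes accumulate into the attributions.
shap_sampling <- function(model, x_expl, background, n_perm, seed) {
  d <- ncol(x_expl)
  n_e <- nrow(x_expl)
  n_b <- nrow(background)
  phi <- matrix(0, n_e, d)
  with_seed(seed, {
    for (e in seq_len(n_e)) {
      for (p in seq_len(n_perm)) {
        perm <- sample.int(d)
        # stack of d+1 coalition states, each n_b background rows
        big <- background[rep(seq_len(n_b), d + 1L), , drop = FALSE]
        cur <- background
        for (step in seq_len(d)) {
          cur[, perm[step]] <- x_expl[e, perm[step]]
          big[(step * n_b + 1L):((step + 1L) * n_b), ] <- cur
        }
        pr <- predict_matrix(model, big)
        vals <- colMeans(matrix(pr, n_b, d + 1L))
        phi[e, perm] <- phi[e, perm] + diff(vals)
      }
    }
  })
  phi / n_perm
}
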