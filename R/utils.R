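# Internal helpers shared across modules: seeded evaluation, stratified fold
# assignment, and the rank-statistic AUC.

#' @importFrom stats rnorm runif sd var predict quantile cor pf plogis glm
#'   binomial coef
#' @importFrom utils head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  All randomness in the package flows through
# this so fixed seeds give bit-identical results.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stream child seed from a parent seed and a stream index,
# kept inside the 32-bit signed range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + 7919 * as.double(index)) %% 2147483647)
}

# Stratified fold assignment: within each class, subjects are shuffled with
# the seed and dealt round-robin, keeping per-fold class counts within one of
# the global ratio.  Returns an integer fold id per row.
stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k < 2) stop("need at least 2 folds")
  if (min(table(labels)) < k) {
    stop("number of folds exceeds the minority-class count")
  }
  folds <- integer(n)
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Mann-Whitney rank AUC with half credit for ties: probability that a random
# positive outranks a random negative.
rank_auc <- function(probs, labels, positive = "schizophrenia") {
  y <- labels == positive
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(probs, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
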