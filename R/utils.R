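# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library functions do not perturb user
# scripts. seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive `n` reproducible child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Rank-based AUC (equivalent to the Mann-Whitney statistic, ties count 0.5).
# `labels` is logical/0-1 with TRUE/1 the positive class; larger scores are
# taken to indicate the positive class.
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment: returns an integer vector of fold ids per
# sample, balancing each class across folds.
stratified_folds <- function(y, k, seed = NULL) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop("each class needs at least as many samples as folds for stratification")
  }
  with_seed(seed, {
    fold <- integer(length(y))
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Column variances without forming a copy per column.
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("at least two rows required to compute column variances")
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

# Deterministic sign convention for principal directions: the entry of
# largest magnitude is made positive (ties resolved to the lowest index,
# which is what which.max returns).
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
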