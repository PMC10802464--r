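# Fixtures and independent oracles used across the suite.

toy_collection <- function() {
  pathway_collection(
    ids = c("P1", "P2", "P3"),
    names = c("alpha pathway", "beta pathway", "gamma pathway"),
    members = list(c("A", "B", "C"), c("C", "D"), c("E", "F", "G", "H")))
}

# A small unit-variance-scaled data matrix with named molecules.
scaled_toy <- function(n = 12, molecules = LETTERS[1:8], seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * length(molecules)), n,
              dimnames = list(paste0("s", seq_len(n)), molecules))
  uv_scale(x)
}

# --- independent oracles -------------------------------------------------

# Benjamini-Hochberg step-up written directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating all group
# assignments of the pooled values (no ties assumed).
mwu_exact_oracle <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    ga <- pool[idx]
    gb <- pool[-idx]
    sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
  }
  u_obs <- u_of(seq_len(na))
  mu <- na * length(b) / 2
  combos <- utils::combn(length(pool), na)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Sequential univariate-y PLS from the closed-form NIPALS limit (w is the
# normalised X'y of the deflated matrices); independent of the package's
# iterative implementation.
pls_oracle <- function(X, y, ncomp) {
  X <- scale(X, scale = FALSE)
  y <- y - mean(y)
  J <- ncol(X)
  W <- matrix(0, J, ncomp)
  V <- matrix(0, J, ncomp)
  cvec <- numeric(ncomp)
  ssy <- numeric(ncomp)
  for (r in seq_len(ncomp)) {
    w <- drop(crossprod(X, y))
    w <- w / sqrt(sum(w^2))
    tt <- drop(X %*% w)
    cc <- sum(y * tt) / sum(tt^2)
    v <- drop(crossprod(X, tt)) / sum(tt^2)
    W[, r] <- w; V[, r] <- v; cvec[r] <- cc
    ssy[r] <- sum(tt^2) * cc^2
    X <- X - tcrossprod(tt, v)
    y <- y - tt * cc
  }
  list(beta = drop(W %*% solve(crossprod(V, W)) %*% cvec),
       W = W, ssy = ssy)
}
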