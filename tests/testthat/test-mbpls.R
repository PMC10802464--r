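make_blocks <- function(n = 60, j1 = 8, j2 = 6, seed = 41, signal = TRUE) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  b1 <- matrix(rnorm(n * j1), n, dimnames = list(paste0("s", 1:n),
                                                 paste0("a", 1:j1)))
  b2 <- matrix(rnorm(n * j2), n, dimnames = list(paste0("s", 1:n),
                                                 paste0("b", 1:j2)))
  if (signal) {
    b1[, 1] <- b1[, 1] + y * 4
    b2[, 1] <- b2[, 1] + y * 4
  }
  list(blocks = list(one = b1, two = b2), y = y)
}

test_that("MB-VIP satisfies its normalisation identity on any fit", {
  d <- make_blocks()
  for (R in 1:3) {
    fit <- fit_multiview(d$blocks, d$y, ncomp = R)
    mv <- mb_vip(fit)
    f <- sum(vapply(fit$W, nrow, integer(1)))
    expect_equal(sum(mv$importance^2) / (f * 2), 1, tolerance = 1e-10)
    # within-block weights have unit norm per LV
    for (Wk in fit$W) {
      expect_equal(unname(colSums(Wk^2)), rep(1, R), tolerance = 1e-10)
    }
  }
})

test_that("superscores are mutually orthogonal under superscore deflation", {
  d <- make_blocks(n = 80, j1 = 12, j2 = 9, seed = 43)
  fit <- fit_multiview(d$blocks, d$y, ncomp = 4)
  G <- crossprod(fit$T_super)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("identical blocks share importance equally; shares sum to one", {
  d <- make_blocks(seed = 45)
  twin <- list(one = d$blocks$one, two = d$blocks$one)
  fit <- fit_multiview(twin, d$y, ncomp = 2)
  bi <- block_importance(fit, per_lv = TRUE)
  expect_equal(bi$importance, rep(0.5, 4), tolerance = 1e-8)
  fit2 <- fit_multiview(d$blocks, d$y, ncomp = 2)
  per_lv <- matrix(block_importance(fit2, per_lv = TRUE)$importance, 2)
  expect_equal(colSums(per_lv), c(1, 1), tolerance = 1e-10)
  agg <- block_importance(fit2, per_lv = FALSE)
  expect_equal(sum(agg$importance), 1, tolerance = 1e-10)
})

test_that("an uninformative block loses importance as the signal grows", {
  set.seed(47)
  n <- 120
  y <- rep(0:1, length.out = n)
  noise <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("n", 1:6)))
  share <- vapply(c(0.5, 1, 2), function(a) {
    sig <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("s", 1:6)))
    sig[, 1:3] <- sig[, 1:3] + a * y
    fit <- fit_multiview(list(sig = sig, noise = noise), y, ncomp = 1)
    bi <- block_importance(fit, per_lv = TRUE)
    bi$importance[bi$block == "noise"]
  }, numeric(1))
  expect_true(all(diff(share) < 0))
  expect_lt(share[3], 0.1)
})

test_that("MB-VIP reduces to VIP in the degenerate concatenated case", {
  # concatenating both blocks into a single-block PLS with R=1 gives the
  # same LV-1 prediction direction up to block weighting
  d <- make_blocks(seed = 49)
  fit_mb <- fit_multiview(d$blocks, d$y, ncomp = 1)
  X <- cbind(scale(d$blocks$one), scale(d$blocks$two))
  fit_sb <- fit_pls(X, d$y, ncomp = 1)
  dir_mb <- unlist(lapply(names(fit_mb$W), function(k) {
    fit_mb$W[[k]][, 1] * fit_mb$A[k, 1]
  }))
  dir_sb <- fit_sb$W[, 1]
  ang <- abs(sum(dir_mb * dir_sb)) /
    sqrt(sum(dir_mb^2) * sum(dir_sb^2))
  expect_gt(ang, 0.98)
})

test_that("prediction is exact in-sample for separable data, chance under null", {
  d <- make_blocks(n = 100, seed = 51)
  fit <- fit_multiview(d$blocks, d$y, ncomp = 2)
  pr <- predict(fit, d$blocks)
  expect_equal(pathpls:::rank_auc(pr$score, d$y == 1), 1)
  expect_equal(dim(pr$superscores), c(100, 2))

  # permuted labels predict held-out data at chance over seeds
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    yp <- sample(d$y)
    tr <- seq_len(60)
    fit0 <- fit_multiview(lapply(d$blocks, function(b) b[tr, ]), yp[tr],
                          ncomp = 1)
    pr0 <- predict(fit0, lapply(d$blocks, function(b) b[-tr, ]))
    pathpls:::rank_auc(pr0$score, yp[-tr] == 1)
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("input contracts: single block, sample mismatch, missing columns", {
  d <- make_blocks()
  expect_error(fit_multiview(d$blocks[1], d$y), "at least 2 blocks")
  short <- d$blocks
  short$two <- short$two[1:30, ]
  expect_error(fit_multiview(short, d$y), "same samples")
  fit <- fit_multiview(d$blocks, d$y, ncomp = 1)
  broken <- d$blocks
  broken$one <- broken$one[, -1]
  expect_error(predict(fit, broken), "lacks")
})

test_that("bootstrap block importances are seeded and near-degenerate for twins", {
  d <- make_blocks(n = 50, seed = 53)
  twin <- list(one = d$blocks$one, two = d$blocks$one + 0)
  bb <- bootstrap_block_importance(twin, d$y, ncomp = 1, n_boot = 20, seed = 2)
  expect_true(all(bb$sd < 1e-8))       # symmetric twins stay at 0.5 exactly
  expect_equal(bb$mean, rep(0.5, 2), tolerance = 1e-8)
  bb2 <- bootstrap_block_importance(twin, d$y, ncomp = 1, n_boot = 20, seed = 2)
  expect_identical(bb, bb2)
  # informative data: bootstrap mean close to the full-data value
  bb3 <- bootstrap_block_importance(d$blocks, d$y, ncomp = 1, n_boot = 30,
                                    seed = 3)
  expect_true(all(abs(bb3$mean - bb3$importance) <=
                    2 * bb3$sd / sqrt(30) * sqrt(30) + 0.1))
})

test_that("latent-variable selection prefers fewer LVs on ties and 1 for 1 factor", {
  set.seed(55)
  n <- 80
  y <- rep(0:1, length.out = n)
  b1 <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("a", 1:6)))
  b2 <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("b", 1:6)))
  b1[, 1:2] <- b1[, 1:2] + 2 * y
  b2[, 1:2] <- b2[, 1:2] + 2 * y
  sel <- select_n_latent(list(b1, b2), y, candidates = 1:3, folds = 4,
                         seed = 5)
  expect_equal(sel$ncomp, 1)
  expect_equal(sel$cv_curve$ncomp, 1:3)

  # two orthogonal spiked directions need two LVs
  set.seed(57)
  yc <- rnorm(n)                       # continuous response, 2 factors
  f2 <- rnorm(n)
  c1 <- matrix(rnorm(n * 8, sd = 0.2), n, dimnames = list(NULL, paste0("a", 1:8)))
  c2 <- matrix(rnorm(n * 8, sd = 0.2), n, dimnames = list(NULL, paste0("b", 1:8)))
  c1[, 1:4] <- c1[, 1:4] + yc
  c2[, 1:4] <- c2[, 1:4] + f2
  y2 <- yc + 2 * f2
  sel2 <- select_n_latent(list(c1, c2), y2, candidates = 1:3, folds = 4,
                          seed = 6)
  expect_gte(sel2$ncomp, 2)
})
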