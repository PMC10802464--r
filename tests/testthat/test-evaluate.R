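test_that("Mann-Whitney U behaves on identities and matches enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- mwu_test(a, b)
  expect_equal(res$p.value, 0.1)            # 2 * 1/20, exact enumeration
  expect_equal(res$statistic, 0)            # every b beats every a
  # U_a + U_b = n_a * n_b
  res_b <- mwu_test(b, a)
  expect_equal(res$statistic + res_b$statistic, 9)
  # identical groups: p near 1
  expect_gt(mwu_test(1:6, 1:6)$p.value, 0.9)
  expect_error(mwu_test(numeric(0), 1:3), "non-empty")

  set.seed(101)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(6) + 0.5
    expect_equal(mwu_test(x, y)$p.value, mwu_exact_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Fisher majority rule combines only past the 50% threshold", {
  # 1 of 4 significant -> combined p set to 1 exactly
  expect_identical(fisher_combine_with_majority_rule(c(0.01, 0.2, 0.3, 0.4)), 1)
  # both significant: chi-square survival of -2*sum(log p) with 2m df
  p2 <- fisher_combine_with_majority_rule(c(0.05, 0.05))
  expect_equal(p2, pchisq(-2 * 2 * log(0.05), df = 4, lower.tail = FALSE))
  # overwhelming evidence propagates
  expect_lt(fisher_combine_with_majority_rule(rep(1e-12, 4)), 1e-12)
  expect_warning(fisher_combine_with_majority_rule(c(0, 0)), "floored")
  expect_error(fisher_combine_with_majority_rule(c(0.2, 1.4)), "\\[0, 1\\]")

  # exhaustive check of the majority gate for m <= 6
  for (m in 1:6) {
    for (k in 0:m) {
      p <- c(rep(0.01, k), rep(0.5, m - k))
      out <- fisher_combine_with_majority_rule(p)
      if (k / m >= 0.5) expect_lt(out, 1) else expect_identical(out, 1)
    }
  }
})

test_that("detection scoring produces coherent confusion counts and AUC", {
  p <- c(T1 = 0.001, A = 1, B = 1, C = 1)
  d <- detection_score(p, "T1")
  expect_equal(unlist(d[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 0, tn = 3, fn = 0))
  expect_equal(d$balanced_rate, 1)
  expect_equal(d$rank_auc, 1)

  p2 <- c(T1 = 1, A = 0.01, B = 0.2, C = 0.6)
  d2 <- detection_score(p2, "T1")
  expect_equal(d2$tp, 0)
  expect_equal(d2$fn, 1)
  expect_equal(d2$fp, 1)
  expect_equal(d2$tp + d2$fp + d2$tn + d2$fn, 4)

  # rank AUC equals the brute-force pairwise count on a 10-pathway toy
  set.seed(103)
  p10 <- setNames(runif(10), paste0("P", 1:10))
  p10["P4"] <- p10["P7"]                  # force a tie
  d10 <- detection_score(p10, "P4")
  others <- p10[names(p10) != "P4"]
  brute <- (sum(others > p10["P4"]) + 0.5 * sum(others == p10["P4"])) / 9
  expect_equal(d10$rank_auc, brute)
  expect_error(detection_score(p10, "absent"), "target")
})

test_that("cross-validated AUC is leak-free and calibrated", {
  cfg <- synthetic_config(n_samples = 120, n_pathways = 8, pathway_size = 8,
                          overlap_frac = 0, rho = 0.5, seed = 105)
  base <- generate_base(cfg)
  sp <- spike_in(base$blocks, base$y, base$collection, "P02", 3, seed = 106)
  builder <- function(b, y) fit_multiview(b, y, ncomp = 1,
                                          collection = base$collection)
  cv <- crossvalidated_auc(sp$blocks, sp$y, builder, folds = 4, repeats = 2,
                           seed = 107)
  expect_length(cv$aucs, 8)               # repeat x fold count honoured
  expect_gt(cv$mean_auc, 0.95)            # strong spike: near-perfect
  expect_true(cv$ci[1] <= cv$mean_auc && cv$mean_auc <= cv$ci[2])

  # null labels: the same pipeline scores held-out data at chance
  yp <- with(list(), {set.seed(108); sample(sp$y)})
  cv_null <- crossvalidated_auc(sp$blocks, yp, builder, folds = 4,
                                repeats = 2, seed = 109)
  expect_gt(cv_null$mean_auc, 0.35)
  expect_lt(cv_null$mean_auc, 0.65)
})

test_that("post-split test-only corruption cannot raise held-out AUC", {
  # a pipeline that leaked test data into any fitted state could exploit a
  # feature equal to y injected into the test portion only; a leak-free
  # pipeline stays at chance under null labels
  cfg <- synthetic_config(n_samples = 100, n_pathways = 8, pathway_size = 8,
                          overlap_frac = 0, rho = 0.4, seed = 115)
  base <- generate_base(cfg)
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    y <- sample(rep(0:1, 50))
    tr <- sort(sample(100, 60))
    btr <- lapply(base$blocks, function(b) as.matrix(b)[tr, ])
    bte <- lapply(base$blocks, function(b) as.matrix(b)[-tr, ])
    bte[[1]][, 1] <- 5 * y[-tr]          # corrupt the test portion only
    fit <- fit_multiview(btr, y[tr], ncomp = 1,
                         collection = base$collection)
    pathpls:::rank_auc(predict(fit, bte)$score, y[-tr] == 1)
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("superscore-metadata correlation flags real associations only", {
  d <- local({
    set.seed(111)
    n <- 80
    y <- rep(0:1, 40)
    b1 <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("a", 1:6)))
    b2 <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("b", 1:6)))
    b1[, 1:3] <- b1[, 1:3] + 1.5 * y
    b2[, 1:3] <- b2[, 1:3] + 1.5 * y
    list(fit = fit_multiview(list(b1, b2), y, ncomp = 2), y = y)
  })
  md <- data.frame(
    mirror = d$fit$T_super[, 1],                    # identical to LV1
    mono = exp(d$fit$T_super[, 1]),                 # monotone transform
    noise = rnorm(80),
    const = rep(1, 80))
  res <- superscore_metadata_correlation(d$fit, md)
  r_mirror <- res$rho[res$lv == 1 & res$variable == "mirror"]
  expect_equal(r_mirror, 1)
  # Spearman is rank-invariant under monotone transforms
  expect_equal(res$rho[res$lv == 1 & res$variable == "mono"], 1)
  expect_true(is.na(res$rho[res$lv == 1 & res$variable == "const"]))
  expect_true(res$flagged[res$lv == 1 & res$variable == "mirror"])
  expect_false(any(res$flagged[res$variable == "noise"]))
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(113)
  sc <- rnorm(50)
  lab <- rbinom(50, 1, 0.5)
  sc[lab == 1] <- sc[lab == 1] + 0.8
  expect_equal(pathpls:::rank_auc(sc, lab == 1),
               as.numeric(suppressMessages(pROC::auc(lab, sc))),
               tolerance = 1e-12)
})
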