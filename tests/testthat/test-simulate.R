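small_config <- function(...) {
  synthetic_config(n_samples = 100, n_pathways = 6, pathway_size = 8,
                   overlap_frac = 0.25, rho = 0.5, seed = 71, ...)
}

test_that("config validation rejects infeasible layouts", {
  expect_error(synthetic_config(pathway_size = 2), "at least 3")
  expect_error(synthetic_config(rho = 1), "rho")
  expect_error(synthetic_config(overlap_frac = 0.99), "infeasible|overlap")
})

test_that("the generator realises the requested correlation structure", {
  cfg0 <- synthetic_config(n_samples = 500, n_pathways = 8, pathway_size = 10,
                           overlap_frac = 0, rho = 0, seed = 73)
  b0 <- generate_base(cfg0)
  X0 <- cbind(as.matrix(b0$blocks[[1]]), as.matrix(b0$blocks[[2]]))
  mean_cor <- function(base, id) {
    cc <- cor(X0[, pathway_members(base$collection, id)])
    mean(cc[upper.tri(cc)])
  }
  r0 <- mean(vapply(b0$collection$ids, mean_cor, numeric(1), base = b0))
  expect_lt(abs(r0), 0.05)

  cfg6 <- synthetic_config(n_samples = 500, n_pathways = 8, pathway_size = 10,
                           overlap_frac = 0, rho = 0.6, seed = 73)
  b6 <- generate_base(cfg6)
  X0 <- cbind(as.matrix(b6$blocks[[1]]), as.matrix(b6$blocks[[2]]))
  r6 <- mean(vapply(b6$collection$ids, mean_cor, numeric(1), base = b6))
  expect_gt(r6, 0.5)
  expect_lt(r6, 0.7)

  # determinism and balanced labels
  b6b <- generate_base(cfg6)
  expect_identical(as.matrix(b6$blocks[[1]]), as.matrix(b6b$blocks[[1]]))
  expect_equal(sum(b6$y == 1), 250)

  # overlapping layout shares molecules between consecutive pathways
  bo <- generate_base(small_config())
  shared <- intersect(pathway_members(bo$collection, "P01"),
                      pathway_members(bo$collection, "P02"))
  expect_equal(length(shared), 2)  # 25% of 8
  # every pathway spans both blocks
  for (id in bo$collection$ids) {
    mem <- pathway_members(bo$collection, id)
    expect_true(any(mem %in% colnames(bo$blocks[[1]])))
    expect_true(any(mem %in% colnames(bo$blocks[[2]])))
  }
})

test_that("spike-in shifts exactly the target cells by alpha", {
  base <- generate_base(small_config())
  target <- "P03"
  mem <- pathway_members(base$collection, target)
  sp <- spike_in(base$blocks, base$y, base$collection, target, 0.5, seed = 5)
  # label shuffle preserves the multiset of labels
  expect_equal(sort(sp$y), sort(base$y))
  changed <- 0L
  for (k in seq_along(base$blocks)) {
    delta <- as.matrix(sp$blocks[[k]]) - as.matrix(base$blocks[[k]])
    hit <- intersect(mem, colnames(base$blocks[[k]]))
    expect_equal(unname(delta[sp$case_idx, hit]),
                 matrix(0.5, length(sp$case_idx), length(hit)),
                 ignore_attr = TRUE, tolerance = 1e-12)
    delta[sp$case_idx, hit] <- 0
    expect_true(all(delta == 0))
    changed <- changed + length(sp$case_idx) * length(hit)
  }
  expect_equal(changed, length(sp$case_idx) * length(mem))

  # alpha = 0 leaves the data identical (shuffle only)
  sp0 <- spike_in(base$blocks, base$y, base$collection, target, 0, seed = 5)
  expect_identical(as.matrix(sp0$blocks[[1]]), as.matrix(base$blocks[[1]]))

  # additive on log2 scale = multiplicative 2^alpha on raw scale
  raw_case <- 2^as.matrix(sp$blocks[[1]])[sp$case_idx[1], mem[mem %in%
    colnames(sp$blocks[[1]])][1]]
  raw_base <- 2^as.matrix(base$blocks[[1]])[sp$case_idx[1], mem[mem %in%
    colnames(base$blocks[[1]])][1]]
  expect_equal(raw_case / raw_base, 2^0.5)

  expect_error(spike_in(base$blocks, base$y, base$collection, "nope", 1),
               "not in collection")
  expect_error(spike_in(base$blocks, base$y, base$collection, target, -1),
               "alpha")
})

test_that("spike-in group means shift by alpha within sampling error", {
  cfg <- synthetic_config(n_samples = 500, n_pathways = 6, pathway_size = 10,
                          overlap_frac = 0, rho = 0.3, seed = 77)
  base <- generate_base(cfg)
  sp <- spike_in(base$blocks, base$y, base$collection, "P02", 0.5, seed = 6)
  X <- cbind(as.matrix(sp$blocks[[1]]), as.matrix(sp$blocks[[2]]))
  case <- seq_len(nrow(X)) %in% sp$case_idx
  mem <- pathway_members(base$collection, "P02")
  for (m in mem) {
    d <- mean(X[case, m]) - mean(X[!case, m])
    se <- sqrt(var(X[, m]) * (1 / sum(case) + 1 / sum(!case)))
    expect_lt(abs(d - 0.5), 3 * se)
  }
  # non-member group differences centred at zero across realisations
  other <- setdiff(colnames(X), unlist(lapply(mem, identity)))
  dnull <- vapply(1:50, function(s) {
    spn <- spike_in(base$blocks, base$y, base$collection, "P02", 0.5,
                    seed = 100 + s)
    Xn <- as.matrix(spn$blocks[[1]])
    cn <- seq_len(nrow(Xn)) %in% spn$case_idx
    m <- setdiff(colnames(Xn), mem)[1]
    mean(Xn[cn, m]) - mean(Xn[!cn, m])
  }, numeric(1))
  expect_lt(abs(mean(dnull)), 0.05)
})

test_that("realisation sweeps are seeded, exhaustive, and shuffle per pathway", {
  base <- generate_base(small_config())
  sw <- realisation_sweep(base$blocks, base$y, base$collection,
                          alphas = c(0.2, 0.8), pathways = c("P01", "P02", "P03"),
                          seed = 9)
  expect_length(sw, 6)
  expect_named(sw, c("P01_a0.2", "P01_a0.8", "P02_a0.2", "P02_a0.8",
                     "P03_a0.2", "P03_a0.8"))
  sw2 <- realisation_sweep(base$blocks, base$y, base$collection,
                           alphas = c(0.2, 0.8),
                           pathways = c("P01", "P02", "P03"), seed = 9)
  expect_identical(sw$P02_a0.8$blocks, sw2$P02_a0.8$blocks)
  # same shuffle across alphas of one pathway, distinct across pathways
  expect_identical(sw$P01_a0.2$y, sw$P01_a0.8$y)
  expect_false(identical(sw$P01_a0.2$y, sw$P02_a0.2$y))
})
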