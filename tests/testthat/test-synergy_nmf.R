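test_that("NMF reconstructs an exactly factorable matrix and respects its domain", {
  set.seed(10)
  W0 <- matrix(runif(8 * 2, 0.2, 1), 8)
  C0 <- matrix(runif(2 * 300, 0.2, 1), 2)
  M <- W0 %*% C0
  fit <- nmf(M, 2, seed = 1, n_restarts = 5)
  expect_gt(fit$vaf_global, 99.9)
  expect_true(all(fit$W >= 0) && all(fit$C >= 0))
  expect_equal(unname(sqrt(colSums(fit$W^2))), rep(1, 2), tolerance = 1e-9)

  # capacity: full-rank factorization beats any smaller N
  resid_full <- nmf(M, 8, seed = 1, n_restarts = 3)$residual
  resid_small <- nmf(M, 1, seed = 1, n_restarts = 3)$residual
  expect_lte(resid_full, resid_small)

  Mneg <- M; Mneg[1, 1] <- -1
  expect_error(nmf(Mneg, 2), "non-negative")
  expect_error(nmf(M, 0), "outside")
  expect_error(nmf(M, 9), "outside")
})

test_that("multiplicative updates never increase the residual or break non-negativity", {
  for (s in 1:3) {
    set.seed(s)
    M <- matrix(runif(6 * 200), 6)
    fit <- nmf(M, 3, seed = s, n_restarts = 1, max_iter = 200)
    expect_true(all(diff(fit$residual_trace) <= 1e-10))
    expect_true(all(fit$W >= 0) && all(fit$C >= 0))
  }
})

test_that("fixed-weighting refits recover held-out activations", {
  # near-indicator weightings: each synergy dominated by one muscle
  W_fixed <- diag(4) * 0.95 + 0.05 / 4
  set.seed(21)
  C0 <- matrix(runif(4 * 400, 0.1, 1), 4)
  M_test <- W_fixed %*% C0
  C_hat <- update_activations_fixed_w(M_test, W_fixed, seed = 2)
  expect_true(all(C_hat >= 0))
  expect_gt(vaf(M_test, W_fixed %*% C_hat, "global"), 99.9)
  for (i in 1:4)
    expect_gt(stats::cor(C_hat[i, ], M_test[i, ]), 0.99)
  expect_error(update_activations_fixed_w(M_test, W_fixed[1:3, ]), "match")
})

test_that("VAF uses uncentered sums of squares at both scopes", {
  orig <- rbind(c(1, 2), c(3, 4))
  recon <- rbind(c(1, 2), c(3, 0))
  expect_equal(vaf(orig, recon, "global"), 100 * (1 - 16 / 30))
  expect_equal(vaf(orig, orig, "global"), 100)
  expect_equal(vaf(orig, orig * 0, "global"), 0)
  pm <- vaf(orig, recon, "per_muscle")
  expect_equal(unname(pm), c(100, 100 * (1 - 16 / 25)))
  expect_error(vaf(orig, recon[1, , drop = FALSE]), "identical shapes")
  expect_error(vaf(matrix(0, 2, 2), matrix(0, 2, 2), "global"), "all zero")
})

test_that("cross-validation splits 30 cycles into 18 train / 12 test and is seed-deterministic", {
  sim <- small_gait(seed = 5)
  M <- sim$M[, 1:3000]
  vt1 <- cross_validated_vaf(M, n_range = 4:5, n_repeats = 3, seed = 9,
                             n_restarts = 1, max_iter = 100)
  expect_equal(vt1$n_train, 18)
  expect_equal(vt1$n_test, 12)
  expect_true(all(vt1$global <= 100))
  expect_true(all(vt1$summary$global_lower <= vt1$summary$global_mean))
  expect_true(all(vt1$summary$global_upper >= vt1$summary$global_mean))
  vt2 <- cross_validated_vaf(M, n_range = 4:5, n_repeats = 3, seed = 9,
                             n_restarts = 1, max_iter = 100)
  expect_identical(vt1$global, vt2$global)
  expect_error(cross_validated_vaf(M, n_range = 4, n_repeats = 1), "n_repeats")
})

test_that("a rank-4 construction passes the VAF thresholds at N=4 but not at N=3", {
  # well-separated narrow bumps so the rank-3 approximation clearly misses
  cfg <- synth_config(n_synergies = 4, n_cycles = 30, noise_sd = 0.005,
                      centers = c(10, 35, 60, 85), widths = rep(5, 4),
                      seed = 13)
  W <- make_weightings(12, 4, seed = 13)
  C <- make_activations(cfg)$C
  M <- synthesize_emg(W, C, noise_sd = 0.005, seed = 13)$M
  vt <- cross_validated_vaf(M, n_range = 3:4, n_repeats = 5, seed = 1,
                            n_restarts = 2)
  s <- vt$summary
  expect_lt(s$global_lower[s$n_synergies == 3], 90)
  expect_gt(s$global_lower[s$n_synergies == 4], 90)
  expect_gt(s$muscle_lower_min[s$n_synergies == 4], 75)
  expect_equal(select_num_synergies(vt), 4)
})

test_that("synergy-number selection applies the strict CI-lower-bound rule", {
  mk <- function(global_lower, muscle_lower_min) {
    structure(list(summary = data.frame(
      n_synergies = seq_along(global_lower),
      global_mean = global_lower + 1, global_lower = global_lower,
      global_upper = global_lower + 2,
      muscle_lower_min = muscle_lower_min)), class = "vaf_table")
  }
  # both rules first satisfied at N=4
  expect_equal(select_num_synergies(mk(c(50, 70, 85, 95, 97),
                                       c(40, 60, 80, 90, 95))), 4)
  # global passes at 3 but one muscle holds out until 5
  expect_equal(select_num_synergies(mk(c(50, 80, 92, 95, 97),
                                       c(40, 60, 70, 74, 80))), 5)
  # boundary values are not "exceeded"
  expect_error(select_num_synergies(mk(c(90, 90), c(75, 75))),
               class = "synstab_no_selection")
  err <- tryCatch(select_num_synergies(mk(50, 50)), condition = identity)
  expect_s3_class(err$table, "vaf_table")
})

test_that("row shuffling preserves per-muscle distributions but destroys structure", {
  sim <- small_gait(seed = 6)
  M <- sim$M[, 1:2000]
  S <- shuffle_control(M, seed = 4)
  for (i in seq_len(nrow(M)))
    expect_equal(sort(S[i, ]), sort(M[i, ]))
  mean_abs_cor <- function(m) {
    cc <- abs(stats::cor(t(m))); mean(cc[upper.tri(cc)])
  }
  expect_lt(mean_abs_cor(S), mean_abs_cor(M))
})

test_that("weighting normalization rescales without changing the product", {
  W <- cbind(c(3, 4, 0), c(0, 0, 2))
  C <- matrix(runif(2 * 10), 2)
  nz <- normalize_synergy(W, C)
  expect_equal(nz$W[, 1], c(0.6, 0.8, 0))
  expect_equal(nz$C[1, ], C[1, ] * 5)
  expect_equal(nz$W %*% nz$C, W %*% C, tolerance = 1e-12)
  # already-unit columns unchanged
  nz2 <- normalize_synergy(nz$W, nz$C)
  expect_equal(nz2$W, nz$W)
  expect_error(normalize_synergy(cbind(c(0, 0)), matrix(1, 1, 2)), "degenerate")
})

test_that("cosine similarity and its critical threshold behave as defined", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0, 1), c(1, 1, 0)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  # two-tailed critical Pearson r at alpha 0.01, df 10 rounds to 0.71
  expect_equal(round(critical_similarity_threshold(0.01, 10), 2), 0.71)
})

test_that("synergy matching recovers identity, permutations, and flags non-matches", {
  sim <- small_gait(seed = 8)
  fit <- nmf(sim$M[, 1:3000], 5, seed = 3, n_restarts = 5)

  gr <- match_synergies(list(fit, fit))
  g1 <- gr$group[gr$trial == 1]; g2 <- gr$group[gr$trial == 2]
  expect_equal(g1, g2)
  expect_true(all(!gr$unmatched))
  expect_true(all(gr$similarity > 0.999))

  # column-permuted copy: permutation recovered exactly
  perm <- c(3, 1, 5, 2, 4)
  fitp <- fit
  fitp$W <- fit$W[, perm]; fitp$C <- fit$C[perm, ]
  gr2 <- match_synergies(list(fit, fitp))
  expect_equal(gr2$group[gr2$trial == 2], gr2$group[gr2$trial == 1][perm])
  # within one trial no two synergies share a label
  expect_false(any(duplicated(stats::na.omit(gr2$group[gr2$trial == 2]))))

  # a trial orthogonal to the reference is flagged unmatched
  ortho <- fit
  ortho$W <- diag(12)[, 6:10]
  set.seed(1); ortho$C <- matrix(runif(5 * 3000), 5)
  gr3 <- match_synergies(list(fit, ortho), threshold = 0.999)
  expect_true(all(gr3$unmatched[gr3$trial == 2]))
  expect_error(match_synergies(list(fit, list(W = diag(3), C = matrix(1, 3, 100)))),
               "muscle count")
})
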