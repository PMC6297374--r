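test_that("100 Poincare sections are built with the boundary retention rule", {
  act <- make_activations(synth_config(n_cycles = 30, seed = 2))
  x <- act$C[1, ]                      # 30 strides x 100 points
  secs <- build_sections(x, tau = 20, d = 6)
  expect_length(secs, 100)
  # embedding span 100 samples: the final stride is dropped everywhere,
  # derived from the index arithmetic (k-1)*100 + p + 100 <= 3000
  counts <- vapply(secs, function(s) nrow(s$states), integer(1))
  expect_true(all(counts == 29))
  expect_true(all(counts >= 27))
  # fixed point is the mean state
  expect_equal(secs[[40]]$fixed_point, colMeans(secs[[40]]$states),
               tolerance = 1e-12)
  expect_error(build_sections(x[1:200], tau = 20, d = 6),
               "insufficient strides")
})

test_that("the Jacobian of a noiseless linear stride map is recovered exactly", {
  s_star <- c(1, -2, 0.5, 3, 0, -1)
  A <- rand_rotation(6, 0.9, seed = 11)
  S <- linear_stride_system(A, s_star, 40, noise_sd = 0, seed = 2)
  fit <- fit_jacobian(list(states = S), fixed_point = s_star)
  expect_lt(max(abs(fit$J - A)), 1e-8)
  expect_false(fit$rank_deficient)
  # a generic (non-rotation) matrix also recovers exactly
  A2 <- rand_radius(6, 0.9, seed = 5)
  S2 <- linear_stride_system(A2, s_star, 40, noise_sd = 0, seed = 3)
  expect_lt(max(abs(fit_jacobian(list(states = S2), fixed_point = s_star)$J - A2)),
            1e-8)

  # degenerate: every state at the fixed point -> least-norm J = 0, flagged
  Sd <- matrix(rep(s_star, each = 10), 10)
  rownames(Sd) <- 1:10
  expect_warning(fd <- fit_jacobian(list(states = Sd)), "rank-deficient")
  expect_equal(fd$J, matrix(0, 6, 6))
  expect_true(fd$rank_deficient)
  expect_error(fit_jacobian(list(states = S[1:4, ])), "strides")
})

test_that("spectral radius of a noisy linear stride system is recovered and converges as noise shrinks", {
  ests <- vapply(1:10, function(s) {
    A <- rand_rotation(6, 0.5, seed = s)
    clean <- linear_stride_system(A, rep(0, 6), 30, 0, seed = s)
    nsd <- 0.01 * stats::sd(clean)
    noisy <- linear_stride_system(A, rep(0, 6), 30, nsd, seed = s + 100)
    max_floquet_multiplier(fit_jacobian(list(states = noisy),
                                        fixed_point = rep(0, 6))$J)
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.5) / 0.5, 0.10)

  # error shrinks with the noise level
  err_at <- function(noise_frac) {
    mean(vapply(1:5, function(s) {
      A <- rand_rotation(4, 0.6, seed = s + 20)
      clean <- linear_stride_system(A, rep(0, 4), 40, 0, seed = s)
      noisy <- linear_stride_system(A, rep(0, 4), 40,
                                    noise_frac * stats::sd(clean), seed = s + 50)
      abs(max_floquet_multiplier(fit_jacobian(list(states = noisy),
                                              fixed_point = rep(0, 4))$J) - 0.6)
    }, numeric(1)))
  }
  errs <- c(err_at(0), err_at(0.001), err_at(0.01))
  expect_lt(errs[1], 1e-10)
  expect_true(errs[2] <= errs[3] + 1e-6)
})

test_that("multiplier magnitudes come from the eigen spectrum", {
  expect_equal(max_floquet_multiplier(diag(c(0.5, 0.2, 0.1))), 0.5)
  rot <- matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2)
  expect_equal(max_floquet_multiplier(rot), 1, tolerance = 1e-12)
  # companion matrix of z^2 - z + 0.25: double root at 0.5
  comp <- matrix(c(0, -0.25, 1, 1), 2)
  expect_equal(max_floquet_multiplier(comp), 0.5, tolerance = 1e-7)
  expect_error(max_floquet_multiplier(matrix(1, 2, 3)), "square")
})

test_that("trial summaries and stability verdicts follow the chosen policy", {
  fs <- floquet_summary(rep(0.7, 100))
  expect_equal(fs$mean, 0.7); expect_equal(fs$max, 0.7)
  expect_true(fs$stable)
  mixed <- c(1.2, rep(0.5, 99))
  fm_mean <- floquet_summary(mixed, "mean")
  fm_max <- floquet_summary(mixed, "max")
  expect_equal(fm_mean$mean, 0.507, tolerance = 1e-12)
  expect_equal(fm_max$max, 1.2)
  expect_true(fm_mean$stable)
  expect_false(fm_max$stable)
  expect_lte(fm_mean$mean, fm_mean$max)
})

test_that("fitted maps contract toward the fixed point when multipliers are below one", {
  s_star <- rep(1, 4)
  A <- rand_rotation(4, 0.6, seed = 9)
  S <- linear_stride_system(A, s_star, 40, 0.002, seed = 4)
  fit <- fit_jacobian(list(states = S), fixed_point = s_star)
  expect_lt(max_floquet_multiplier(fit$J), 1)
  dev <- rep(0.5, 4)
  for (i in 1:20) dev <- as.numeric(fit$J %*% dev)
  expect_lt(sqrt(sum(dev^2)), 1e-3)

  # unstable map: deviations grow
  Au <- rand_rotation(4, 1.3, seed = 10)
  Su <- linear_stride_system(Au, s_star, 15, 0, seed = 5, S0 = s_star + 0.001)
  fitu <- fit_jacobian(list(states = Su), fixed_point = s_star)
  expect_gt(max_floquet_multiplier(fitu$J), 1)
  devu <- rep(0.01, 4)
  for (i in 1:20) devu <- as.numeric(fitu$J %*% devu)
  expect_gt(sqrt(sum(devu^2)), 1)
})

test_that("estimated multiplier magnitudes are invariant under similarity transforms", {
  A <- rand_rotation(4, 0.7, seed = 3)
  set.seed(8)
  P <- matrix(rnorm(16), 4) + diag(4) * 2
  B <- P %*% A %*% solve(P)
  Sa <- linear_stride_system(A, rep(0, 4), 40, 1e-4, seed = 6)
  Sb <- linear_stride_system(B, rep(0, 4), 40, 1e-4, seed = 6)
  ma <- max_floquet_multiplier(fit_jacobian(list(states = Sa),
                                            fixed_point = rep(0, 4))$J)
  mb <- max_floquet_multiplier(fit_jacobian(list(states = Sb),
                                            fixed_point = rep(0, 4))$J)
  expect_equal(ma, 0.7, tolerance = 0.05)
  expect_equal(mb, 0.7, tolerance = 0.05)
})
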