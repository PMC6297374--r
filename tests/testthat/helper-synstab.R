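# shared fixture builders (everything is generated in code at test time)

# random rotation-based map with a prescribed spectral radius: every
# eigenvalue has modulus `rho`, so trajectories stay well conditioned
rand_rotation <- function(d, rho, seed) {
  set.seed(seed)
  rho * qr.Q(qr(matrix(rnorm(d * d), d)))
}

# random matrix rescaled to a prescribed spectral radius
rand_radius <- function(d, rho, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  A * rho / max(Mod(eigen(A, only.values = TRUE)$values))
}

# best cosine match of each true weighting column among estimated columns
recovery_cosines <- function(W_est, W_true) {
  vapply(seq_len(ncol(W_true)), function(j)
    max(vapply(seq_len(ncol(W_est)), function(i)
      cosine_similarity(W_est[, i], W_true[, j]), numeric(1L))),
    numeric(1L))
}

# small synthetic envelope set: defaults scaled down for unit tests
small_gait <- function(seed = 1L, n_cycles = 30L, ...) {
  simulate_gait_emg(synth_config(n_cycles = n_cycles, seed = seed, ...))
}
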