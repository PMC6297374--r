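#' Configuration for the synthetic gait-EMG generator
#'
#' Defaults emulate the treadmill-walking recordings the pipeline targets:
#' 12 muscles sampled at 1,000 Hz, 50 gait cycles of roughly 1 s each, with
#' muscle activity driven by 5 non-negative synergies whose activations are
#' one phase-localized bump per cycle (body support, forward propulsion,
#' swing initiation, mid-swing, late swing).  Cycle-to-cycle variability
#' enters through AR(1) dynamics on each bump's center and amplitude; the
#' innovation scales (`phase_jitter_sd`, `amplitude_noise_sd`) control
#' stride-to-stride perturbation size, and `rho` its persistence.
#'
#' @param n_muscles,n_synergies,n_cycles Counts (defaults 12, 5, 52 — the
#'   protocol records over 50 cycles so 50 complete heel-contact-to-heel-contact
#'   cycles remain after the final boundary).
#' @param samples_per_cycle Mean raw-cycle duration in samples at `fs`
#'   (default 1000).
#' @param duration_jitter Relative SD of cycle duration (default 0.1).
#' @param fs Raw sampling rate in Hz (default 1000).
#' @param centers Bump centers in % gait cycle, one per synergy; defaults
#'   place the five synergies at 15, 40, 60, 80 and 97% of the cycle
#'   (loading/support, forward propulsion, swing initiation, mid-swing,
#'   late swing), spaced so each synergy is resolvable by the VAF
#'   selection rule.
#' @param widths Bump SDs in % gait cycle (default 10, 7, 7, 6, 6).
#' @param amplitude_noise_sd AR(1) innovation SD of bump amplitude
#'   (relative to the unit mean amplitude; default 0.10).
#' @param phase_jitter_sd AR(1) innovation SD of bump center in % cycle
#'   (default 1.5).
#' @param rho AR(1) coefficient of the cycle-parameter dynamics
#'   (default 0.3; `0 <= rho < 1`).
#' @param noise_sd Additive measurement-noise SD as a fraction of the clean
#'   signal SD (default 0.05).
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_muscles = 12L, n_synergies = 5L, n_cycles = 52L,
                         samples_per_cycle = 1000L, duration_jitter = 0.1,
                         fs = 1000,
                         centers = NULL, widths = NULL,
                         amplitude_noise_sd = 0.10, phase_jitter_sd = 1.5,
                         rho = 0.3, noise_sd = 0.05, seed = 1L) {
  if (is.null(centers))
    centers <- if (n_synergies == 5L) c(15, 40, 60, 80, 97)
               else seq(15, 95, length.out = n_synergies) %% 100
  if (is.null(widths))
    widths <- rep(c(10, 7, 7, 6, 6), length.out = n_synergies)
  stopifnot(n_synergies <= n_muscles, rho >= 0, rho < 1,
            all(centers >= 0), all(centers < 100),
            amplitude_noise_sd >= 0, phase_jitter_sd >= 0, noise_sd >= 0)
  structure(list(n_muscles = n_muscles, n_synergies = n_synergies,
                 n_cycles = n_cycles, samples_per_cycle = samples_per_cycle,
                 duration_jitter = duration_jitter, fs = fs,
                 centers = centers, widths = widths,
                 amplitude_noise_sd = amplitude_noise_sd,
                 phase_jitter_sd = phase_jitter_sd, rho = rho,
                 noise_sd = noise_sd, seed = seed),
            class = "synth_config")
}

#' Generate ground-truth synergy weightings
#'
#' Seeded rejection sampling of non-negative unit-norm weighting columns
#' with bounded pairwise cosine similarity.  Each synergy gets 2-3 dominant
#' muscles (mimicking plantarflexor, dorsiflexor, support, swing clusters)
#' plus small background weights.
#'
#' @param n_muscles,n_synergies Counts.
#' @param min_separation Upper bound on pairwise cosine similarity
#'   (default 0.6).
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget (default 200).
#' @return Muscles x synergies matrix, unit-norm columns.
#' @export
make_weightings <- function(n_muscles = 12L, n_synergies = 5L,
                            min_separation = 0.6, seed = 1L,
                            max_attempts = 200L) {
  if (n_synergies > n_muscles) stop("more synergies than muscles")
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    W <- matrix(runif(n_muscles * n_synergies, 0, 0.15), n_muscles)
    # spread the dominant muscles across synergies
    pool <- sample(n_muscles)
    for (i in seq_len(n_synergies)) {
      n_dom <- sample(2:3, 1L)
      idx <- ((i - 1L) * 2L + seq_len(n_dom) - 1L) %% n_muscles + 1L
      W[pool[idx], i] <- runif(n_dom, 0.7, 1)
    }
    W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
    cosines <- crossprod(W)
    if (max(cosines[upper.tri(cosines)]) < min_separation) return(W)
  }
  stop(sprintf("could not reach pairwise cosine < %.2f in %d attempts",
               min_separation, max_attempts))
}

# AR(1) path of length n: x_c = rho * x_{c-1} + sd * innovation
.ar1 <- function(n, rho, sd) {
  x <- numeric(n)
  for (c in seq_len(n)) x[c] <- rho * (if (c > 1L) x[c - 1L] else 0) + sd * rnorm(1L)
  x
}

#' Generate ground-truth synergy activations
#'
#' One circular Gaussian bump per synergy per cycle on the 100-point phase
#' grid; each cycle's bump center and amplitude follow seeded AR(1)
#' dynamics around the configured means, so strides vary but the mean cycle
#' is fixed.  Bumps wrap across the cycle boundary (circular continuity).
#'
#' @param config A [synth_config()].
#' @return List with `C` (synergies x `n_cycles * 100`, non-negative) and
#'   `parameters` (data frame: cycle, synergy, center, amplitude).
#' @export
make_activations <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  n_syn <- config$n_synergies; n_cyc <- config$n_cycles
  phases <- 0:99
  C <- matrix(0, n_syn, n_cyc * 100L)
  logs <- vector("list", n_syn)
  for (i in seq_len(n_syn)) {
    d_center <- .ar1(n_cyc, config$rho, config$phase_jitter_sd)
    d_amp <- .ar1(n_cyc, config$rho, config$amplitude_noise_sd)
    centers <- (config$centers[i] + d_center) %% 100
    amps <- pmax(1 + d_amp, 0.05)
    for (k in seq_len(n_cyc)) {
      dist_circ <- (phases - centers[k] + 50) %% 100 - 50
      C[i, ((k - 1L) * 100L + 1L):(k * 100L)] <-
        amps[k] * exp(-dist_circ^2 / (2 * config$widths[i]^2))
    }
    logs[[i]] <- data.frame(cycle = seq_len(n_cyc), synergy = i,
                            center = centers, amplitude = amps)
  }
  list(C = C, parameters = do.call(rbind, logs))
}

#' Synthesize an envelope-level EMG matrix from known synergies
#'
#' `M = W %*% C + noise`, with Gaussian noise scaled to a fraction of the
#' clean signal SD and the result clipped at zero (rectified envelopes are
#' non-negative; the clipping bias is negligible at the default 5% noise).
#'
#' @param W_true Muscles x synergies weightings.
#' @param C_true Synergies x T activations.
#' @param noise_sd Noise SD as a fraction of `sd(W %*% C)` (default 0.05).
#' @param seed Integer seed.
#' @return List with `M` (muscles x T, non-negative), `clean`, `W_true`,
#'   `C_true`.
#' @export
synthesize_emg <- function(W_true, C_true, noise_sd = 0.05, seed = 1L) {
  clean <- W_true %*% C_true
  set.seed(seed + 2L)
  noise <- matrix(rnorm(length(clean), sd = noise_sd * stats::sd(clean)),
                  nrow(clean))
  M <- pmax(clean + noise, 0)
  list(M = M, clean = clean, W_true = W_true, C_true = C_true)
}

#' Generate a complete synthetic gait-EMG data set
#'
#' Combines [make_weightings()], [make_activations()] and
#' [synthesize_emg()].  With `raw = TRUE` the envelope matrix is additionally
#' rendered as a raw-EMG-like recording: each cycle's envelopes are
#' up-sampled to a jittered duration at `fs`, multiplied by zero-mean
#' wideband carrier noise (so the 40 Hz high-pass / rectify / 10 Hz
#' low-pass chain recovers the envelope), and heel-contact indices are
#' derived from the cumulative cycle durations.
#'
#' @param config A [synth_config()].
#' @param raw Also produce the raw-EMG-like [emg_recording()] (default
#'   FALSE).
#' @return List with `M` (muscles x T envelope matrix), `W_true`, `C_true`,
#'   `parameters`, `config`, and when `raw = TRUE` also `recording`.
#' @export
simulate_gait_emg <- function(config = synth_config(), raw = FALSE) {
  W <- make_weightings(config$n_muscles, config$n_synergies, seed = config$seed)
  act <- make_activations(config)
  emg <- synthesize_emg(W, act$C, config$noise_sd, config$seed)
  out <- list(M = emg$M, W_true = W, C_true = act$C,
              parameters = act$parameters, config = config)
  if (raw) {
    set.seed(config$seed + 3L)
    durations <- pmax(round(config$samples_per_cycle *
                              (1 + config$duration_jitter * rnorm(config$n_cycles))),
                      200L)
    total <- sum(durations)
    raw_mat <- matrix(0, total, config$n_muscles)
    pos <- 1L
    hc <- integer(config$n_cycles)
    for (k in seq_len(config$n_cycles)) {
      hc[k] <- pos
      cols <- ((k - 1L) * 100L + 1L):(k * 100L)
      grid_in <- (0:99) / 100 * durations[k]
      for (m in seq_len(config$n_muscles)) {
        env_k <- stats::approx(grid_in, emg$M[m, cols],
                               xout = 0:(durations[k] - 1L), rule = 2)$y
        carrier <- rnorm(durations[k])
        raw_mat[pos:(pos + durations[k] - 1L), m] <- env_k * carrier
      }
      pos <- pos + durations[k]
    }
    out$recording <- emg_recording(raw_mat, fs = config$fs,
                                   channels = paste0("m", seq_len(config$n_muscles)),
                                   heel_contacts = hc)
  }
  out
}

#' Logistic map series
#'
#' `x[t+1] = r * x[t] * (1 - x[t])`.  At `r = 4` the map is chaotic with
#' maximum Lyapunov exponent exactly `ln 2` per step, the standard
#' closed-form oracle for Lyapunov estimators.
#'
#' @param r Growth parameter, `0 < r <= 4`.
#' @param x0 Initial state in `(0, 1)`.
#' @param n Series length.
#' @return Numeric series of length `n`, values in `[0, 1]`.
#' @export
logistic_map <- function(r, x0, n) {
  stopifnot(r > 0, r <= 4, x0 > 0, x0 < 1, n >= 1)
  x <- numeric(n)
  x[1L] <- x0
  for (t in seq_len(n - 1L)) x[t + 1L] <- r * x[t] * (1 - x[t])
  x
}

#' Linear stride-to-stride system
#'
#' `S[k+1] = S* + A (S[k] - S*) + noise`, a discrete linear map whose
#' spectral radius is the exact maximum Floquet multiplier — the oracle for
#' the Jacobian-fitting estimator.
#'
#' @param A d x d state matrix.
#' @param S_star Fixed point (length d).
#' @param n_strides Number of strides to simulate.
#' @param noise_sd Additive Gaussian noise SD (default 0).
#' @param seed Integer seed.
#' @param S0 Initial state; default `S_star + 1` in every coordinate.
#' @return `n_strides` x d matrix of stride states (rownames = stride
#'   index).
#' @export
linear_stride_system <- function(A, S_star, n_strides, noise_sd = 0,
                                 seed = 1L, S0 = NULL) {
  A <- as.matrix(A)
  d <- nrow(A)
  stopifnot(ncol(A) == d, length(S_star) == d)
  if (is.null(S0)) S0 <- S_star + 1
  set.seed(seed)
  S <- matrix(NA_real_, n_strides, d)
  S[1L, ] <- S0
  for (k in seq_len(n_strides - 1L))
    S[k + 1L, ] <- S_star + as.numeric(A %*% (S[k, ] - S_star)) +
      rnorm(d, sd = noise_sd)
  rownames(S) <- seq_len(n_strides)
  S
}
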