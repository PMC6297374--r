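#' Average mutual information of a series with its lagged copy
#'
#' AMI is estimated from the joint histogram of `(x_t, x_{t+lag})` on
#' `n_bins` equal-width bins spanning the observed range, in bits.  The
#' curve's first local minimum is the conventional embedding delay.
#'
#' @param x Numeric series (non-constant).
#' @param max_lag Largest lag evaluated (default 100, one stride on the
#'   100-points-per-cycle grid); must be below `length(x) / 2`.
#' @param n_bins Histogram bins (default 16).
#' @return An `ami_curve`: numeric vector of AMI values (bits) for lags
#'   `0..max_lag`, with attribute `lags`.
#' @export
average_mutual_information <- function(x, max_lag = 100L, n_bins = 16L) {
  x <- as.numeric(x)
  n <- length(x)
  if (max_lag >= n / 2) stop("max_lag must be below half the series length")
  rng <- range(x)
  if (diff(rng) == 0) stop("zero entropy: series is constant")
  bins <- pmin(findInterval(x, seq(rng[1L], rng[2L], length.out = n_bins + 1L),
                            rightmost.closed = TRUE), n_bins)
  ami <- vapply(0:max_lag, function(lag) {
    a <- bins[1:(n - lag)]; b <- bins[(1 + lag):n]
    joint <- table(a, b) / (n - lag)
    pa <- rowSums(joint); pb <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / outer(pa, pb)[nz]))
  }, numeric(1L))
  structure(ami, lags = 0:max_lag, class = "ami_curve")
}

#' First local minimum of a curve
#'
#' The smallest lag `m` with `curve[m] < curve[m-1]` and
#' `curve[m] <= curve[m+1]` (plateaus resolve to their first index).  If no
#' interior local minimum exists, the global minimum over positive lags is
#' returned with `fallback = TRUE`.
#'
#' @param curve Numeric vector indexed from lag 0 (length >= 3).
#' @return List with `lag` (integer) and `fallback` (logical).
#' @export
first_local_minimum <- function(curve) {
  curve <- as.numeric(curve)
  n <- length(curve)
  if (n < 3L) stop("curve must have at least 3 points")
  for (m in 2:(n - 1L)) {       # position m = lag m - 1
    if (curve[m] < curve[m - 1L] && curve[m] <= curve[m + 1L])
      return(list(lag = m - 1L, fallback = FALSE))
  }
  list(lag = which.min(curve[-1L]), fallback = TRUE)
}

#' Select the embedding delay from the AMI curve
#'
#' @param x Numeric series.
#' @param max_lag,n_bins Passed to [average_mutual_information()].
#' @return List with `tau` (samples; 1 sample = 1% gait cycle on the
#'   normalized grid), `fallback`, and the `ami` curve.
#' @export
select_delay <- function(x, max_lag = 100L, n_bins = 16L) {
  ami <- average_mutual_information(x, max_lag, n_bins)
  fm <- first_local_minimum(ami)
  list(tau = fm$lag, fallback = fm$fallback, ami = ami)
}

#' Global false nearest neighbors
#'
#' Kennel's criterion: the nearest neighbor of each point in dimension `d`
#' is false if the extra distance introduced by the `(d+1)`-th delay
#' coordinate exceeds `Rtol` times the dimension-`d` distance, or if the
#' `(d+1)`-dimensional distance exceeds `Atol` times the series SD (the
#' attractor size).  The fraction of false neighbors per `d` drops to ~0 at
#' a sufficient embedding dimension.
#'
#' @param x Numeric series.
#' @param tau Embedding delay in samples.
#' @param d_max Largest dimension tested (default 8).
#' @param Rtol,Atol Kennel tolerances (defaults 15 and 2).
#' @return Numeric vector of FNN fractions for `d = 1..d_max`.
#' @export
false_nearest_neighbors <- function(x, tau, d_max = 8L, Rtol = 15, Atol = 2) {
  x <- as.numeric(x)
  n <- length(x)
  n_use <- n - d_max * tau          # points embeddable up to d_max + 1 coords
  if (n_use < 10L) stop("series too short to embed at d_max")
  sd_x <- stats::sd(x)
  fractions <- numeric(d_max)
  for (d in seq_len(d_max)) {
    emb <- delay_embed(x[seq_len(n_use + (d - 1L) * tau)], tau, d)
    emb <- emb[seq_len(n_use), , drop = FALSE]
    dm <- as.matrix(stats::dist(emb))
    diag(dm) <- Inf
    nn <- apply(dm, 1L, which.min)
    rd <- dm[cbind(seq_len(n_use), nn)]
    extra <- abs(x[seq_len(n_use) + d * tau] - x[nn + d * tau])
    rd1 <- sqrt(rd^2 + extra^2)
    # the distance-ratio test is meaningless for numerically coincident
    # neighbors (recurrences of the same state): such pairs are genuine
    floor_d <- 1e-8 * sd_x
    false_nb <- (rd > floor_d & extra / rd > Rtol) | (rd1 > Atol * sd_x)
    fractions[d] <- mean(false_nb)
  }
  fractions
}

#' Select the embedding dimension from FNN fractions
#'
#' The smallest dimension whose FNN fraction is at or below `threshold`;
#' if none qualifies, the argmin with a fallback flag.  `unified` overrides
#' the data-driven choice with a fixed dimension (the convention of
#' unifying the dimension across subjects; 6 for synergy activations).
#'
#' @param fnn_fractions FNN fractions for `d = 1..d_max`.
#' @param threshold Acceptance fraction (default 0.01).
#' @param unified Optional fixed dimension overriding the selection.
#' @return List with `d` (integer), `fallback`, `unified` (logical).
#' @export
select_embedding_dimension <- function(fnn_fractions, threshold = 0.01,
                                       unified = NULL) {
  if (!is.null(unified))
    return(list(d = as.integer(unified), fallback = FALSE, unified = TRUE))
  ok <- which(fnn_fractions <= threshold)
  if (length(ok) > 0L)
    list(d = ok[1L], fallback = FALSE, unified = FALSE)
  else
    list(d = which.min(fnn_fractions), fallback = TRUE, unified = FALSE)
}

#' Delay-coordinate embedding
#'
#' Builds the trajectory `S(t) = (x_t, x_{t+tau}, ..., x_{t+(d-1)tau})`.
#'
#' @param x Numeric series of length `> (d-1) * tau`.
#' @param tau Delay in samples (>= 1).
#' @param d Embedding dimension (>= 1).
#' @return A `delay_embedding`: matrix of `length(x) - (d-1)*tau` rows and
#'   `d` columns, with attributes `tau`, `d`, `source_length`.
#' @export
delay_embed <- function(x, tau, d) {
  x <- as.numeric(x)
  tau <- as.integer(tau); d <- as.integer(d)
  if (tau < 1L || d < 1L) stop("tau and d must be >= 1")
  n <- length(x)
  m <- n - (d - 1L) * tau
  if (m < 1L) stop(sprintf("series of %d samples too short for d = %d, tau = %d", n, d, tau))
  traj <- vapply(0:(d - 1L), function(k) x[(1L + k * tau):(m + k * tau)], numeric(m))
  traj <- matrix(traj, nrow = m)
  structure(traj, tau = tau, d = d, source_length = n,
            class = c("delay_embedding", "matrix", "array"))
}

#' Choose embedding parameters for one activation series
#'
#' Delay from the first AMI minimum; dimension from global FNN, optionally
#' overridden by a unified dimension.
#'
#' @param x Numeric series.
#' @param unified_d Fixed dimension override (default 6, the unified value
#'   for synergy activations); `NULL` for fully data-driven selection.
#' @param max_lag,n_bins AMI controls.
#' @param d_max,Rtol,Atol,threshold FNN controls.
#' @return List with `tau`, `d`, `tau_fallback`, `d_fallback`, `unified`,
#'   `fnn_fractions`.
#' @export
select_embedding <- function(x, unified_d = 6L, max_lag = 100L, n_bins = 16L,
                             d_max = 8L, Rtol = 15, Atol = 2, threshold = 0.01) {
  del <- select_delay(x, max_lag, n_bins)
  if (is.null(unified_d)) {
    fnn <- false_nearest_neighbors(x, del$tau, d_max, Rtol, Atol)
    dim_sel <- select_embedding_dimension(fnn, threshold)
  } else {
    fnn <- NULL
    dim_sel <- select_embedding_dimension(numeric(0), threshold, unified = unified_d)
  }
  list(tau = del$tau, d = dim_sel$d, tau_fallback = del$fallback,
       d_fallback = dim_sel$fallback, unified = dim_sel$unified,
       fnn_fractions = fnn)
}
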