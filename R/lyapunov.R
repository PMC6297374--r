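#' Nearest-neighbor pairs with a Theiler exclusion window
#'
#' For each trajectory point, the Euclidean nearest neighbor among points
#' whose time index differs by more than `theiler_window` samples, so that
#' temporally adjacent (trivially correlated) points cannot pair.  Ties are
#' broken toward the smaller index.
#'
#' @param trajectory Numeric matrix, states in rows (a [delay_embed()]
#'   result or any points-in-rows matrix).
#' @param theiler_window Exclusion half-width in samples (default 100, one
#'   stride at 100 points per cycle — the mean-period rule).
#' @return Integer matrix with columns `j` (point) and `k` (its neighbor),
#'   one row per point.
#' @export
nearest_neighbor_pairs <- function(trajectory, theiler_window = 100L) {
  traj <- as.matrix(trajectory)
  n <- nrow(traj)
  if (n <= 2L * theiler_window)
    stop(sprintf("trajectory of %d points too short for a Theiler window of %d",
                 n, theiler_window))
  dm <- as.matrix(stats::dist(traj))
  idx <- seq_len(n)
  for (j in idx) {
    lo <- max(1L, j - theiler_window); hi <- min(n, j + theiler_window)
    dm[j, lo:hi] <- Inf
  }
  nn <- max.col(-dm, ties.method = "first")
  cbind(j = idx, k = nn)
}

#' Mean log-divergence curve of nearest-neighbor pairs
#'
#' Tracks each pair `(j, k)` forward `i = 0..horizon` steps and averages
#' `ln ||S[j+i] - S[k+i]||` over all pairs still inside the data; pairs
#' whose initial distance is exactly zero carry no divergence information
#' and are dropped.
#'
#' @param trajectory Numeric matrix of states in rows.
#' @param pairs Index pairs from [nearest_neighbor_pairs()].
#' @param horizon Number of forward steps (default 1000, i.e. 10 strides).
#' @return A `divergence_curve`: list with `mean_log_divergence` (length
#'   `horizon + 1`, step `i` at position `i + 1`), `n_pairs` per step, and
#'   `delta_t = 1` sample (1% gait cycle).
#' @export
divergence_curve <- function(trajectory, pairs, horizon = 1000L) {
  traj <- as.matrix(trajectory)
  n <- nrow(traj)
  if (horizon < 1L) stop("horizon must be >= 1")
  j <- pairs[, 1L]; k <- pairs[, 2L]
  d0 <- sqrt(rowSums((traj[j, , drop = FALSE] - traj[k, , drop = FALSE])^2))
  keep <- d0 > 0
  j <- j[keep]; k <- k[keep]
  if (length(j) == 0L) stop("no nonzero-distance pairs at step 0")
  mld <- rep(NA_real_, horizon + 1L)
  np <- integer(horizon + 1L)
  for (i in 0:horizon) {
    ok <- (j + i) <= n & (k + i) <= n
    np[i + 1L] <- sum(ok)
    if (np[i + 1L] > 0L) {
      dd <- sqrt(rowSums((traj[j[ok] + i, , drop = FALSE] -
                          traj[k[ok] + i, , drop = FALSE])^2))
      mld[i + 1L] <- mean(log(dd[dd > 0]))
    }
  }
  structure(list(mean_log_divergence = mld, n_pairs = np, delta_t = 1),
            class = "divergence_curve")
}

#' Short-term maximum Lyapunov exponent
#'
#' Ordinary least-squares slope of the mean log-divergence curve over the
#' 0-to-1-stride window (both endpoints included), scaled from per-sample
#' to per-stride units.  Positive values indicate local instability.
#'
#' @param curve A [divergence_curve()].
#' @param samples_per_stride Samples per stride (default 100).
#' @param fit_steps Steps included in the fit; default `0:samples_per_stride`.
#' @return A `lyapunov_result`: list with `lambda` (nats per stride),
#'   `slope_per_sample`, `r_squared`, `fit_steps`, `units`.
#' @export
max_lyapunov_short <- function(curve, samples_per_stride = 100L,
                               fit_steps = NULL) {
  stopifnot(inherits(curve, "divergence_curve"))
  if (is.null(fit_steps)) fit_steps <- 0:samples_per_stride
  y <- curve$mean_log_divergence[fit_steps + 1L]
  if (anyNA(y))
    stop("divergence curve does not cover the requested fit window")
  fit <- stats::lm(y ~ fit_steps)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(fit_steps, y)^2
  structure(list(lambda = slope * samples_per_stride,
                 slope_per_sample = slope, r_squared = r2,
                 fit_steps = range(fit_steps),
                 units = "nats/stride"),
            class = "lyapunov_result")
}

#' @export
print.lyapunov_result <- function(x, ...) {
  cat(sprintf("<lyapunov_result> lambda* = %.4f %s (R^2 = %.3f, fit %d..%d samples)\n",
              x$lambda, x$units, x$r_squared, x$fit_steps[1L], x$fit_steps[2L]))
  invisible(x)
}

#' Lyapunov exponent of a scalar series (convenience wrapper)
#'
#' Embeds the series, finds Theiler-excluded nearest neighbors, builds the
#' divergence curve and fits the short-term exponent.
#'
#' @param x Numeric series (e.g. one synergy activation, 100 points/cycle).
#' @param tau,d Embedding parameters.
#' @param theiler_window Neighbor exclusion window (default 100).
#' @param horizon Divergence-curve length (default 1000 when the series
#'   allows, otherwise trimmed).
#' @param samples_per_stride,fit_steps Passed to [max_lyapunov_short()].
#' @return A `lyapunov_result` with the embedding recorded.
#' @export
lyapunov_exponent <- function(x, tau, d, theiler_window = 100L,
                              horizon = 1000L, samples_per_stride = 100L,
                              fit_steps = NULL) {
  emb <- delay_embed(x, tau, d)
  pairs <- nearest_neighbor_pairs(emb, theiler_window)
  horizon <- min(horizon, nrow(emb) - 1L)
  curve <- divergence_curve(emb, pairs, horizon)
  res <- max_lyapunov_short(curve, samples_per_stride, fit_steps)
  res$tau <- tau; res$d <- d
  res$curve <- curve
  res
}
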