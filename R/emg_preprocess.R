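#' EMG recording container
#'
#' Bundles a raw multi-channel surface-EMG recording with its sampling rate,
#' channel names and the right-heel-contact event indices that delimit gait
#' cycles.  All downstream preprocessing starts from this object.
#'
#' @param samples Numeric matrix, samples x channels, signed amplitudes in
#'   arbitrary voltage units.
#' @param fs Sampling rate in Hz (scalar, > 0).
#' @param channels Character vector of channel (muscle) names, one per
#'   column of `samples`.
#' @param heel_contacts Integer vector of right-heel-contact sample indices,
#'   1-based, strictly increasing, all within `1..nrow(samples)`.
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channels, heel_contacts) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("EMG samples must be numeric and finite (no NA/NaN/Inf)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive sampling rate in Hz")
  channels <- as.character(channels)
  if (length(channels) != ncol(samples))
    stop(sprintf("%d channel names for %d channels", length(channels),
                 ncol(samples)))
  heel_contacts <- as.integer(heel_contacts)
  if (any(diff(heel_contacts) <= 0))
    stop("heel-contact indices must be strictly increasing")
  if (any(heel_contacts < 1L) || any(heel_contacts > nrow(samples)))
    stop("heel-contact indices fall outside the recording")
  structure(list(samples = samples, fs = fs, channels = channels,
                 heel_contacts = heel_contacts),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz, %d heel contacts\n",
              nrow(x$samples), ncol(x$samples), x$fs, length(x$heel_contacts)))
  invisible(x)
}

#' Read an EMG recording from delimited text
#'
#' The EMG file holds one header row of channel names and one row per
#' sample; the events file is a single column of heel-contact indices
#' (0-based by default, matching typical event-detection exports, or in
#' seconds with `events_unit = "seconds"`).
#'
#' @param emg_file Path to a CSV of EMG samples (header = channel names).
#' @param events_file Path to a single-column CSV of heel-contact events.
#' @param fs Sampling rate in Hz.
#' @param events_unit `"samples0"` (0-based indices, default), `"samples1"`
#'   (1-based) or `"seconds"`.
#' @return An [emg_recording()].
#' @export
read_emg_recording <- function(emg_file, events_file, fs,
                               events_unit = c("samples0", "samples1", "seconds")) {
  events_unit <- match.arg(events_unit)
  if (!file.exists(emg_file)) stop("EMG file not found: ", emg_file)
  if (!file.exists(events_file)) stop("events file not found: ", events_file)
  dat <- utils::read.csv(emg_file, check.names = FALSE)
  ev <- utils::read.csv(events_file, header = FALSE)[[1L]]
  hc <- switch(events_unit,
               samples0 = as.integer(ev) + 1L,
               samples1 = as.integer(ev),
               seconds  = as.integer(round(ev * fs)) + 1L)
  emg_recording(as.matrix(dat), fs = fs, channels = colnames(dat),
                heel_contacts = hc)
}

# Odd (point-reflected) end padding, the standard filtfilt edge treatment:
# extends the series at both ends so the filter transient decays in the
# padding, not in the data.
.reflect_pad <- function(x, n_pad) {
  n <- length(x)
  if (n_pad >= n)
    stop(sprintf("signal too short to filter: %d samples for %d padding", n, n_pad))
  head_ext <- 2 * x[1L] - x[(n_pad + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - n_pad)]
  c(head_ext, x, tail_ext)
}

#' Zero-lag Butterworth filter
#'
#' Applies a fourth-order Butterworth filter forward and backward so the net
#' phase shift is zero (the magnitude response is squared, i.e. effectively
#' eighth order).  Ends are extended by odd reflection over three times the
#' filter length before filtering and trimmed afterwards.
#'
#' @param x Numeric vector, or matrix with one channel per column.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist rate.
#' @param mode `"high"` or `"low"`.
#' @param order Filter order for a single pass (default 4).
#' @return Filtered series, same shape as the input.
#' @export
filter_zero_lag <- function(x, fs, cutoff, mode = c("high", "low"), order = 4L) {
  mode <- match.arg(mode)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop(sprintf("cutoff %g Hz is not inside (0, Nyquist = %g Hz)", cutoff, fs / 2))
  bf <- signal::butter(order, cutoff / (fs / 2), type = ifelse(mode == "high", "high", "low"))
  n_pad <- 3L * (order + 1L)
  # start each pass in steady state for the first sample (past inputs at
  # x[1], past outputs at DC-gain * x[1]) so no start-up transient occurs
  dc_gain <- sum(bf$b) / sum(bf$a)
  pass <- function(v)
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1L], length(bf$b) - 1L),
                              init.y = rep(dc_gain * v[1L], length(bf$a) - 1L)))
  one <- function(v) {
    vp <- .reflect_pad(v, n_pad)
    f1 <- pass(vp)
    f2 <- rev(pass(rev(f1)))
    f2[(n_pad + 1L):(n_pad + length(v))]
  }
  if (is.matrix(x)) apply(x, 2L, one) else one(x)
}

#' Full-wave rectification
#'
#' @param x Numeric vector or matrix.
#' @return Elementwise absolute value.
#' @export
rectify <- function(x) {
  if (any(!is.finite(x))) stop("non-finite values in signal")
  abs(x)
}

#' Split a recording into gait cycles
#'
#' Cycle `k` runs from heel contact `k` up to (but excluding) heel contact
#' `k + 1`, so consecutive cycles tile the record without overlap.
#'
#' @param envelopes Samples x channels matrix (or vector).
#' @param heel_contacts Strictly increasing 1-based sample indices, at
#'   least two.
#' @return A list of `length(heel_contacts) - 1` matrices.
#' @export
segment_cycles <- function(envelopes, heel_contacts) {
  if (is.vector(envelopes)) envelopes <- matrix(envelopes, ncol = 1L)
  if (length(heel_contacts) < 2L)
    stop("need at least 2 heel contacts to delimit one cycle")
  if (any(diff(heel_contacts) <= 0))
    stop("heel-contact indices must be strictly increasing")
  if (utils::tail(heel_contacts, 1L) > nrow(envelopes) + 1L)
    stop("heel-contact index beyond end of data")
  lapply(seq_len(length(heel_contacts) - 1L), function(k) {
    envelopes[heel_contacts[k]:(heel_contacts[k + 1L] - 1L), , drop = FALSE]
  })
}

#' Time-normalize one gait cycle to 100 phase points
#'
#' Linear interpolation onto the phase grid `k/100` of the cycle duration,
#' `k = 0..99`; the endpoint is excluded so consecutive normalized cycles
#' tile without duplicating the heel-contact sample.
#'
#' @param segment Matrix (samples x channels) or vector covering one cycle.
#' @param n_points Points per cycle (default 100).
#' @return `n_points` x channels matrix.
#' @export
time_normalize <- function(segment, n_points = 100L) {
  if (is.vector(segment)) segment <- matrix(segment, ncol = 1L)
  len <- nrow(segment)
  if (len < 2L) stop("cycle segment must have at least 2 samples")
  # sample i sits at time i-1; the next heel contact is at time `len`
  grid <- (seq_len(n_points) - 1L) / n_points * len
  apply(segment, 2L, function(v)
    stats::approx(x = seq_len(len) - 1L, y = v, xout = grid, rule = 2)$y)
}

#' Assemble a cycle tensor from a recording's envelopes
#'
#' @param envelopes Samples x channels envelope matrix.
#' @param heel_contacts Heel-contact indices (1-based).
#' @param n_points Phase points per cycle.
#' @return A `cycle_tensor`: array `[cycle, phase, muscle]`, all values >= 0.
#' @export
cycle_tensor <- function(envelopes, heel_contacts, n_points = 100L) {
  segs <- segment_cycles(envelopes, heel_contacts)
  arr <- array(NA_real_,
               dim = c(length(segs), n_points, ncol(segs[[1L]])),
               dimnames = list(NULL, NULL, colnames(segs[[1L]])))
  for (k in seq_along(segs)) arr[k, , ] <- time_normalize(segs[[k]], n_points)
  structure(arr, class = c("cycle_tensor", "array"))
}

#' Retain the analysis cycles
#'
#' Drops the first `drop_head` cycles (gait initiation), keeps the next
#' `keep`, and requires at least `drop_tail` cycles after them (gait
#' termination), mirroring the treadmill protocol of >50 recorded cycles
#' with the first and last 10 excluded and 30 analyzed.
#'
#' @param tensor A `cycle_tensor`.
#' @param drop_head,drop_tail,keep Cycle counts (defaults 10, 10, 30).
#' @return The retained `cycle_tensor` of `keep` cycles.
#' @export
select_cycles <- function(tensor, drop_head = 10L, drop_tail = 10L, keep = 30L) {
  n <- dim(tensor)[1L]
  need <- drop_head + keep + drop_tail
  if (n < need)
    stop(sprintf("insufficient cycles: %d recorded, need >= %d (%d head + %d keep + %d tail)",
                 n, need, drop_head, keep, drop_tail))
  out <- tensor[(drop_head + 1L):(drop_head + keep), , , drop = FALSE]
  structure(out, class = c("cycle_tensor", "array"))
}

#' Flatten a cycle tensor to a muscles x time matrix
#'
#' @param tensor A `cycle_tensor` `[cycle, phase, muscle]`.
#' @return Muscles x (cycles * phase points) matrix; cycles are concatenated
#'   in time order.
#' @export
flatten_cycles <- function(tensor) {
  d <- dim(tensor)
  out <- matrix(NA_real_, nrow = d[3L], ncol = d[1L] * d[2L])
  for (m in seq_len(d[3L])) out[m, ] <- as.numeric(t(tensor[, , m]))
  rownames(out) <- dimnames(tensor)[[3L]]
  out
}

#' Peak and unit-variance normalization of the EMG matrix
#'
#' Step 1 divides each muscle row by its own maximum; step 2 divides each
#' row by its (population) standard deviation so every muscle has unit
#' variance.  Both divisors are kept in the normalization record so either
#' convention can be audited or inverted.
#'
#' @param mat Non-negative muscles x T matrix (T a multiple of the phase
#'   grid length).
#' @param peak_scope `"per_muscle"` (each row by its own peak, default) or
#'   `"global"` (all rows by the single largest value).
#' @return An `emg_matrix`: list with `values`, `muscles`, `cycles_kept`,
#'   and `normalization` (`peak`, `sd` per muscle).
#' @export
normalize_emg_matrix <- function(mat, peak_scope = c("per_muscle", "global")) {
  peak_scope <- match.arg(peak_scope)
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("EMG matrix must be non-negative before normalization")
  muscles <- rownames(mat)
  if (is.null(muscles)) muscles <- paste0("m", seq_len(nrow(mat)))
  peaks <- if (peak_scope == "global")
    rep(max(mat), nrow(mat)) else apply(mat, 1L, max)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sds0 <- apply(mat, 1L, pop_sd)
  if (any(sds0 == 0))
    stop("degenerate channel (zero variance): ",
         paste(muscles[sds0 == 0], collapse = ", "))
  step1 <- mat / peaks
  sds <- apply(step1, 1L, pop_sd)
  values <- step1 / sds
  rownames(values) <- muscles
  structure(list(values = values, muscles = muscles,
                 cycles_kept = ncol(mat) %/% 100L,
                 normalization = list(peak = peaks, sd = sds,
                                      sd_convention = "population",
                                      peak_scope = peak_scope)),
            class = "emg_matrix")
}

#' @export
print.emg_matrix <- function(x, ...) {
  cat(sprintf("<emg_matrix> %d muscles x %d time steps (%d cycles x 100 phase points)\n",
              nrow(x$values), ncol(x$values), x$cycles_kept))
  invisible(x)
}

#' Run the full EMG preprocessing chain
#'
#' High-pass (40 Hz) -> full-wave rectify -> low-pass (10 Hz), both filters
#' zero-lag fourth-order Butterworth; segment at right heel contacts;
#' time-normalize each cycle to 100 points; drop initiation/termination
#' cycles; concatenate; peak- then SD-normalize each muscle.
#'
#' @param rec An [emg_recording()].
#' @param highpass,lowpass Cutoffs in Hz.
#' @param drop_head,drop_tail,keep Cycle retention rule (see
#'   [select_cycles()]).
#' @param n_points Phase points per cycle.
#' @param peak_scope Passed to [normalize_emg_matrix()].
#' @return An `emg_matrix` (muscles x `keep * n_points`).
#' @export
preprocess_emg <- function(rec, highpass = 40, lowpass = 10,
                           drop_head = 10L, drop_tail = 10L, keep = 30L,
                           n_points = 100L, peak_scope = "per_muscle") {
  stopifnot(inherits(rec, "emg_recording"))
  hp <- filter_zero_lag(rec$samples, rec$fs, highpass, "high")
  rect <- rectify(hp)
  env <- filter_zero_lag(rect, rec$fs, lowpass, "low")
  # low-pass ringing can undershoot zero slightly; envelopes are amplitudes
  env[env < 0] <- 0
  colnames(env) <- rec$channels
  tens <- cycle_tensor(env, rec$heel_contacts, n_points)
  tens <- select_cycles(tens, drop_head, drop_tail, keep)
  normalize_emg_matrix(flatten_cycles(tens), peak_scope = peak_scope)
}
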