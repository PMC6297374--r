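test_that("zero-lag Butterworth filtering removes DC, preserves phase, and meets the analytic stopband", {
  fs <- 1000
  # high-pass removes a constant offset entirely
  const <- rep(3.7, 2000)
  expect_lt(max(abs(filter_zero_lag(const, fs, 40, "high"))), 1e-6)

  # zero-phase: low-passed slow sine cross-correlates with input at lag 0
  t <- 0:2999
  slow <- sin(2 * pi * 1 * t / fs)
  lp <- filter_zero_lag(slow, fs, 10, "low")
  cc <- stats::ccf(lp, slow, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # 200 Hz tone through the 10 Hz low-pass: the analytic squared 4th-order
  # Butterworth magnitude (forward-backward pass) bounds the residual
  fast <- sin(2 * pi * 200 * t / fs)
  out <- filter_zero_lag(fast, fs, 10, "low")
  analytic <- 1 / (1 + (200 / 10)^8)   # |H|^2 of one pass = |H| of two
  expect_lt(max(abs(out[500:2500])), max(1e-6, 10 * analytic))
  expect_lt(max(abs(out[500:2500])), 0.01)

  # parameter validation
  expect_error(filter_zero_lag(slow, fs, 600, "low"), "Nyquist")
  expect_error(filter_zero_lag(rnorm(10), fs, 40, "high"), "too short")
})

test_that("rectification is the idempotent absolute value", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_equal(rectify(rep(0, 5)), rep(0, 5))
  set.seed(1)
  x <- rnorm(100)
  expect_equal(rectify(rectify(x)), rectify(x))
  expect_error(rectify(c(1, NA)), "non-finite")
})

test_that("cycle segmentation partitions heel contact to heel contact", {
  x <- matrix(seq_len(2100), ncol = 1)
  segs <- segment_cycles(x, c(1, 1001, 2101) - 0)   # 1-based starts
  expect_length(segs, 2)
  expect_equal(vapply(segs, nrow, integer(1)), c(1000, 1100))
  expect_equal(sum(vapply(segs, nrow, integer(1))), 2101 - 1)
  expect_length(segment_cycles(x, c(1, 1001)), 1)
  expect_error(segment_cycles(x, 5), "at least 2")
  expect_error(segment_cycles(x, c(10, 5)), "strictly increasing")
})

test_that("time normalization interpolates linearly onto the 100-point grid", {
  ramp <- (0:999) / 1000                      # 0 .. 0.999 over 1000 samples
  tn <- time_normalize(ramp)
  expect_length(tn, 100)
  # closed form: sample i sits at value i/1000, so phase k/100 (time 10k)
  # interpolates to exactly k/100
  expect_equal(as.numeric(tn), (0:99) / 100, tolerance = 1e-12)

  expect_equal(as.numeric(time_normalize(rep(2.5, 731))), rep(2.5, 100))
  expect_length(time_normalize(rnorm(731)), 100)
  expect_error(time_normalize(1), "at least 2")

  # round trip: a cycle already on the 100-point grid reproduces exactly
  set.seed(3)
  cyc <- rnorm(100)
  expect_equal(as.numeric(time_normalize(cyc)), cyc, tolerance = 1e-12)
})

test_that("cycle retention drops initiation and termination cycles", {
  arr <- array(abs(rnorm(50 * 100 * 3)), c(50, 100, 3))
  arr[, 1, 1] <- seq_len(50)  # tag cycles by index
  tens <- structure(arr, class = c("cycle_tensor", "array"))
  kept <- select_cycles(tens)
  expect_equal(dim(kept)[1], 30)
  expect_equal(kept[, 1, 1], 11:40)
  expect_equal(nrow(flatten_cycles(kept)), 3)
  expect_equal(ncol(flatten_cycles(kept)), 3000)
  short <- structure(arr[1:45, , , drop = FALSE], class = c("cycle_tensor", "array"))
  expect_error(select_cycles(short), "insufficient cycles.*45")
})

test_that("peak + unit-variance normalization matches the hand computation", {
  row <- c(0, 1, 2, 3)
  m <- rbind(a = row, b = c(1, 5, 2, 8))
  nm <- normalize_emg_matrix(m)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(unname(nm$normalization$peak["a"]), 3)
  step1 <- row / 3
  expect_equal(unname(nm$values["a", ]), step1 / pop_sd(step1), tolerance = 1e-12)
  # every row has population SD 1
  expect_equal(unname(apply(nm$values, 1, pop_sd)), c(1, 1), tolerance = 1e-9)
  expect_error(normalize_emg_matrix(rbind(a = rep(2, 4), b = c(1, 2, 3, 4))),
               "degenerate channel.*a")
})

test_that("the full preprocessing chain yields the 12 x 3000 analysis matrix and crushes the carrier", {
  sim <- simulate_gait_emg(synth_config(seed = 11), raw = TRUE)
  mat <- preprocess_emg(sim$recording)
  expect_s3_class(mat, "emg_matrix")
  expect_equal(dim(mat$values), c(12, 3000))
  expect_equal(mat$cycles_kept, 30)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(unname(apply(mat$values, 1, pop_sd)), rep(1, 12), tolerance = 1e-9)

  # a pure 200 Hz carrier riding on an envelope is attenuated > 40 dB by the
  # low-pass stage (analytic two-pass Butterworth response is ~ -208 dB)
  fs <- 1000; t <- 0:4999
  carrier <- sin(2 * pi * 200 * t / fs)
  out <- filter_zero_lag(carrier, fs, 10, "low")
  atten_db <- 20 * log10(max(abs(out[1000:4000])) / 1)
  expect_lt(atten_db, -40)
})

test_that("recordings round-trip through delimited text with event-unit conversion", {
  sim <- simulate_gait_emg(synth_config(n_cycles = 52, seed = 2), raw = TRUE)
  emg_f <- tempfile(fileext = ".csv"); ev_f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(sim$recording$samples), emg_f, row.names = FALSE)
  write.table(sim$recording$heel_contacts - 1L, ev_f, row.names = FALSE,
              col.names = FALSE, sep = ",")
  rec2 <- read_emg_recording(emg_f, ev_f, fs = 1000)
  expect_equal(rec2$heel_contacts, sim$recording$heel_contacts)
  expect_equal(unname(rec2$samples), unname(sim$recording$samples),
               tolerance = 1e-12)
  expect_error(read_emg_recording("nope.csv", ev_f, 1000), "not found")

  # invariant enforcement on construction
  expect_error(emg_recording(matrix(c(1, NA), 1), 1000, c("a", "b"), 1), "finite")
  expect_error(emg_recording(matrix(1:4, 2), 1000, "a", 1), "channel names")
  expect_error(emg_recording(matrix(1:4, 2), 1000, c("a", "b"), c(2, 1)),
               "strictly increasing")
})
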