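#' Ordinary least-squares line fit
#'
#' @param x Predictor (walking speed, km/h); at least two distinct values.
#' @param y Response (stability measure).
#' @return List with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation; 0 when `y` is constant).
#' @export
ols_fit <- function(x, y) {
  if (length(unique(x)) < 2L) stop("need at least 2 distinct x values")
  if (length(x) != length(y)) stop("x and y lengths differ")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}

#' Increasing rates of a stability measure in slow and fast speed bands
#'
#' Regresses the measure on walking speed separately within a slower and a
#' faster band for every subject x synergy, returning both band slopes and
#' their paired difference for downstream testing.  A synergy with fewer
#' than two speeds in a band (e.g. a swing synergy absent at the slowest
#' speeds) is marked not-computed (`NA` slope) rather than zero.
#'
#' @param measures Data frame with columns `subject`, `synergy`, `speed`
#'   (km/h) and `value`.
#' @param slow_band,fast_band Length-2 numeric `c(min, max)` in km/h;
#'   defaults 2.0-5.0 and 5.0-8.0 (the shared 5.0 km/h boundary; set
#'   `fast_band = c(5.5, 8)` for the disjoint-band convention).
#' @return A `trend_table` data frame: per subject x synergy, `slope_slow`,
#'   `slope_fast`, `r2_slow`, `r2_fast`, `slope_diff`, with the band
#'   definitions as attributes.
#' @export
increasing_rates <- function(measures, slow_band = c(2.0, 5.0),
                             fast_band = c(5.0, 8.0)) {
  stopifnot(all(c("subject", "synergy", "speed", "value") %in% names(measures)))
  in_band <- function(sp, band) sp >= band[1L] & sp <= band[2L]
  for (band in list(slow = slow_band, fast = fast_band)) {
    present <- unique(measures$speed[in_band(measures$speed, band)])
    if (length(present) < 2L)
      stop(sprintf("band %.1f-%.1f km/h covered by %d speed(s); need >= 2",
                   band[1L], band[2L], length(present)))
  }
  combos <- unique(measures[, c("subject", "synergy")])
  one_band <- function(sub, syn, band) {
    rows <- measures[measures$subject == sub & measures$synergy == syn &
                       in_band(measures$speed, band) & !is.na(measures$value), ]
    if (length(unique(rows$speed)) < 2L) return(list(slope = NA_real_, r_squared = NA_real_))
    ols_fit(rows$speed, rows$value)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    slow <- one_band(combos$subject[i], combos$synergy[i], slow_band)
    fast <- one_band(combos$subject[i], combos$synergy[i], fast_band)
    data.frame(subject = combos$subject[i], synergy = combos$synergy[i],
               slope_slow = slow$slope, slope_fast = fast$slope,
               r2_slow = slow$r_squared, r2_fast = fast$r_squared,
               slope_diff = fast$slope - slow$slope)
  }))
  structure(out, class = c("trend_table", "data.frame"),
            slow_band = slow_band, fast_band = fast_band)
}
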