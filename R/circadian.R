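#' Hourly activity profile over whole days
#'
#' Truncates a count series to complete 24-hour blocks from its start,
#' averages counts within clock hours, and returns both the sequence of
#' hourly means and the average 24-hour profile. This is the standard
#' preparation for the nonparametric circadian measures IS, IV and RA,
#' which are computed on hourly means of the raw (pre-rank) counts.
#'
#' @param series a [count_series] spanning at least 2 whole days. The
#'   clock hour of the first epoch is taken from `start_time` (midnight
#'   assumed when absent).
#' @return list of class `hourly_profile`: `hourly` (hourly means, in
#'   time order), `clock_hour` (0-23 label per hourly mean), `profile24`
#'   (mean per clock hour, index 1 = hour 0), `n_days`.
#' @export
hourly_profile <- function(series) {
  stopifnot(inherits(series, "count_series"))
  eph <- 3600 / series$epoch_seconds        # epochs per hour
  if (eph < 1 || abs(eph - round(eph)) > 1e-9) {
    stop("hourly_profile: epoch must divide one hour")
  }
  eph <- as.integer(round(eph))
  n_days <- length(series$values) %/% (24L * eph)
  if (n_days < 2L) {
    exclusion_error("insufficient data for circadian measures",
                    series$subject_id, "needs >= 2 whole days")
  }
  v <- series$values[seq_len(n_days * 24L * eph)]
  hourly <- as.numeric(colMeans(matrix(v, nrow = eph)))
  start_hour <- if (is.null(series$start_time)) 0L else
    as.integer(format(series$start_time, "%H", tz = "UTC"))
  clock <- (start_hour + seq_along(hourly) - 1L) %% 24L
  profile24 <- vapply(0:23, function(h) mean(hourly[clock == h]), numeric(1))
  structure(list(hourly = hourly, clock_hour = clock,
                 profile24 = profile24, n_days = n_days),
            class = "hourly_profile")
}

#' Interdaily stability (IS)
#'
#' Ratio of the variance of the average 24-hour profile to the overall
#' variance of the hourly means:
#' `IS = (N * sum_h (xbar_h - xbar)^2) / (24 * sum_i (x_i - xbar)^2)`,
#' with `N` hourly values and `xbar_h` the 24 clock-hour class means.
#' IS lies in `[0, 1]`; 1 means a perfectly repeated daily rhythm, values
#' near `1/n_days` indicate no day-to-day stability. Undefined (NA) for a
#' constant series.
#'
#' @param hp an [hourly_profile()].
#' @return IS, or `NA` when the hourly variance is zero.
#' @export
interdaily_stability <- function(hp) {
  stopifnot(inherits(hp, "hourly_profile"))
  x <- hp$hourly
  n <- length(x)
  tot <- sum((x - mean(x))^2)
  if (tot == 0) return(NA_real_)
  n * sum((hp$profile24 - mean(x))^2) / (24 * tot)
}

#' Intradaily variability (IV)
#'
#' Ratio of the mean squared successive difference of the hourly means to
#' their variance:
#' `IV = (N * sum_{i>=2} (x_i - x_{i-1})^2) / ((N - 1) * sum_i (x_i - xbar)^2)`.
#' IV is ~0 for a smooth rhythm, ~2 for white noise, and approaches 4 for
#' a strictly alternating series; it measures fragmentation of the
#' rest-activity rhythm. Undefined (NA) for a constant series.
#'
#' @param hp an [hourly_profile()].
#' @return IV, or `NA` when the hourly variance is zero.
#' @export
intradaily_variability <- function(hp) {
  stopifnot(inherits(hp, "hourly_profile"))
  x <- hp$hourly
  n <- length(x)
  if (n < 2) stop("intradaily_variability: need at least 2 hourly values")
  tot <- sum((x - mean(x))^2)
  if (tot == 0) return(NA_real_)
  n * sum(diff(x)^2) / ((n - 1) * tot)
}

#' Relative amplitude (RA)
#'
#' Contrast between the most active 10 consecutive hours (M10) and the
#' least active 5 consecutive hours (L5) of the average 24-hour profile,
#' searched circularly: `RA = (M10 - L5) / (M10 + L5)`. RA lies in
#' `[0, 1]` for a nonnegative profile; 1 when the least active window is
#' completely still, 0 for a flat profile. Undefined (NA) when
#' `M10 + L5 = 0`.
#'
#' @param hp an [hourly_profile()].
#' @param m_hours most-active window length (default 10).
#' @param l_hours least-active window length (default 5).
#' @return RA, or `NA` when the profile is all zero.
#' @export
relative_amplitude <- function(hp, m_hours = 10, l_hours = 5) {
  stopifnot(inherits(hp, "hourly_profile"))
  p <- hp$profile24
  wmean <- function(w) {
    ext <- c(p, p[seq_len(w - 1)])   # circular windows
    vapply(1:24, function(s) mean(ext[s:(s + w - 1)]), numeric(1))
  }
  m10 <- max(wmean(m_hours))
  l5 <- min(wmean(l_hours))
  if (m10 + l5 == 0) return(NA_real_)
  (m10 - l5) / (m10 + l5)
}

#' Mean activity
#'
#' Average activity counts per epoch of the (trimmed, unbinned) series.
#'
#' @param series a [count_series].
#' @return mean counts per epoch.
#' @export
mean_activity <- function(series) {
  stopifnot(inherits(series, "count_series"))
  mean(series$values)
}

#' All traditional actigraphy quantifiers for one subject
#'
#' @param series trimmed, unbinned [count_series].
#' @return one-row data frame: `mean_activity`, `is_`, `iv`, `ra` (NA
#'   where undefined).
#' @export
circadian_measures <- function(series) {
  hp <- hourly_profile(series)
  data.frame(mean_activity = mean_activity(series),
             is_ = interdaily_stability(hp),
             iv = intradaily_variability(hp),
             ra = relative_amplitude(hp))
}
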