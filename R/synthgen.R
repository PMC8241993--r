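#' Noisy sine fixture
#'
#' Generates a sine wave contaminated with additive white Gaussian noise at
#' a prescribed signal-to-noise ratio. The SNR is defined as the ratio of
#' the mean squared signal to the noise variance, so for amplitude `A` the
#' noise standard deviation is `sqrt(A^2 / (2 * snr))`. These fixtures make
#' the contrast between rhythm-dominated and noise-dominated recurrence
#' plots reproducible: as the random component grows the plot diffuses and
#' determinism drops.
#'
#' @param n_points number of samples (> 0).
#' @param period samples per cycle (>= 2).
#' @param amplitude signal amplitude `A`.
#' @param snr signal-to-noise ratio (> 0, may be `Inf` for a pure sine).
#' @param seed RNG seed for the noise draw.
#' @return a [count_series] (values may be negative) with 60 s epochs.
#' @examples
#' s <- gen_noisy_sine(400, period = 100, snr = 5, seed = 1)
#' @export
gen_noisy_sine <- function(n_points, period, amplitude = 1, snr = Inf,
                           seed = NULL) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points <= 0) {
    stop("gen_noisy_sine: n_points must be a positive count")
  }
  if (!is.numeric(period) || length(period) != 1L || period < 2) {
    stop("gen_noisy_sine: period must be >= 2 samples")
  }
  if (!(snr > 0)) stop("gen_noisy_sine: snr must be > 0 (or Inf)")
  n_points <- as.integer(n_points)
  t <- seq_len(n_points) - 1L
  signal <- amplitude * sin(2 * pi * t / period)
  noise_sd <- if (is.infinite(snr)) 0 else sqrt(amplitude^2 / (2 * snr))
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n_points, sd = noise_sd))
  } else rep(0, n_points)
  count_series(signal + noise, epoch_seconds = 60,
               subject_id = sprintf("sine_snr%s", format(snr)),
               nonnegative = FALSE)
}

#' Cohort generator specification
#'
#' Parameters of the two-group synthetic actigraphy generator. Each subject
#' gets ~`days` of minute-resolution counts built from (i) a deterministic
#' circadian baseline (a half-sine envelope over the wake window, near-zero
#' at night with runs of exact zeros), (ii) recurrent activity bouts
#' arriving as a Poisson process within the wake window, with
#' gamma-distributed durations and a half-sine within-bout count template
#' (so bouts are repeated local patterns, not flat plateaus), and (iii)
#' rare impulsive spikes emulating restlessness. Group structure enters
#' through the bout duration mean and coefficient of variation: the default
#' depressed ("D") group has shorter and less diverse bouts than the
#' non-depressed ("N") group, with the bout arrival rate scaled so both
#' groups have the same expected total bout time.
#'
#' Group-varying fields (`base_rate`, `bout_rate`, `bout_duration_mean`,
#' `bout_duration_cv`, `bout_gain`) accept a scalar (both groups) or a
#' length-2 vector `(N, D)`.
#'
#' @param n_per_group subjects per group, `(N, D)`; defaults `c(25, 21)`.
#' @param days recording length in days.
#' @param epoch_minutes sampling interval in minutes.
#' @param wake_hours daily wake-window length (hours).
#' @param wake_start_hour clock hour the wake window opens.
#' @param base_rate mean wake-time count level (counts/min) at the peak of
#'   the circadian envelope.
#' @param bout_rate bout arrivals per wake-hour.
#' @param bout_duration_mean mean bout duration (minutes).
#' @param bout_duration_cv coefficient of variation of bout durations.
#' @param bout_gain within-bout count multiplier applied to `base_rate`.
#' @param spike_prob per-epoch probability of an impulsive spike.
#' @param night_zero_prob probability a rest-window epoch is exactly zero.
#' @param night_rate mean of the (small) residual count in non-zero night
#'   epochs.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(25L, 21L),
                        days = 28,
                        epoch_minutes = 1,
                        wake_hours = 16,
                        wake_start_hour = 7,
                        base_rate = 250,
                        bout_rate = c(0.5, 0.5 * 60 / 35),
                        bout_duration_mean = c(60, 35),
                        bout_duration_cv = c(0.6, 0.35),
                        bout_gain = 1.5,
                        spike_prob = 0.005,
                        night_zero_prob = 0.7,
                        night_rate = 8,
                        seed = 1L) {
  two <- function(v, name) {
    if (length(v) == 1L) v <- rep(v, 2L)
    if (length(v) != 2L || any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("cohort_spec: '%s' must be a nonnegative scalar or (N, D) pair", name))
    }
    stats::setNames(as.numeric(v), c("N", "D"))
  }
  if (length(n_per_group) != 2L || any(n_per_group < 0)) {
    stop("cohort_spec: n_per_group must be a pair of counts")
  }
  stopifnot(days > 0, epoch_minutes > 0, wake_hours > 0, wake_hours <= 24,
            spike_prob >= 0, spike_prob <= 1,
            night_zero_prob >= 0, night_zero_prob <= 1)
  structure(list(
    n_per_group = stats::setNames(as.integer(n_per_group), c("N", "D")),
    days = days, epoch_minutes = epoch_minutes,
    wake_hours = wake_hours, wake_start_hour = wake_start_hour,
    base_rate = two(base_rate, "base_rate"),
    bout_rate = two(bout_rate, "bout_rate"),
    bout_duration_mean = two(bout_duration_mean, "bout_duration_mean"),
    bout_duration_cv = two(bout_duration_cv, "bout_duration_cv"),
    bout_gain = two(bout_gain, "bout_gain"),
    spike_prob = spike_prob, night_zero_prob = night_zero_prob,
    night_rate = night_rate, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Simulate one subject's activity-count series
#'
#' @param spec a [cohort_spec].
#' @param group `"N"` (non-depressed) or `"D"` (depressed).
#' @param subject_id identifier stored in the series.
#' @param seed RNG seed for this subject (derived from the spec seed by
#'   [gen_cohort()]).
#' @return a list of class `subject_record` with fields `subject_id`,
#'   `group`, `series` (a [count_series]) and `true_params` (the group's
#'   bout parameters plus the realised bout durations).
#' @export
gen_subject <- function(spec, group, subject_id = group, seed = spec$seed) {
  if (!inherits(spec, "cohort_spec")) stop("gen_subject: spec must be a cohort_spec")
  if (!group %in% c("N", "D")) stop("gen_subject: unknown group label: ", group)
  ep <- spec$epoch_minutes
  n <- as.integer(round(spec$days * 24 * 60 / ep))
  minute_of_day <- ((seq_len(n) - 1L) * ep) %% 1440
  wake_start <- spec$wake_start_hour * 60
  wake_len <- spec$wake_hours * 60
  u <- (minute_of_day - wake_start) / wake_len   # position in wake window
  wake <- u >= 0 & u < 1

  base <- spec$base_rate[[group]]
  baseline <- numeric(n)
  baseline[wake] <- base * sin(pi * u[wake])     # circadian envelope

  with_seed(seed, {
    # Poisson bout arrivals over the whole wake time of the recording
    total_wake_hours <- spec$days * spec$wake_hours
    n_bouts <- stats::rpois(1, spec$bout_rate[[group]] * total_wake_hours)
    bouts <- numeric(n)
    durations <- numeric(0)
    if (n_bouts > 0) {
      cv <- spec$bout_duration_cv[[group]]
      mu <- spec$bout_duration_mean[[group]]
      durations <- if (cv > 0) {
        stats::rgamma(n_bouts, shape = 1 / cv^2, scale = mu * cv^2)
      } else rep(mu, n_bouts)
      durations <- pmax(durations, ep)           # at least one epoch
      # uniform start epochs within the wake window
      wake_idx <- which(wake)
      starts <- sort(sample(wake_idx, n_bouts, replace = TRUE))
      gain <- spec$bout_gain[[group]] * base
      for (b in seq_len(n_bouts)) {
        len <- max(1L, as.integer(round(durations[b] / ep)))
        idx <- starts[b]:min(n, starts[b] + len - 1L)
        s <- seq_along(idx) - 0.5
        bouts[idx] <- bouts[idx] + gain * sin(pi * s / len)
      }
    }

    night <- !wake
    night_vals <- numeric(sum(night))
    nonzero <- stats::runif(sum(night)) >= spec$night_zero_prob
    if (any(nonzero)) {
      night_vals[nonzero] <- stats::rexp(sum(nonzero), rate = 1 / spec$night_rate)
    }
    baseline[night] <- night_vals

    spikes <- numeric(n)
    hit <- stats::runif(n) < spec$spike_prob
    if (any(hit)) spikes[hit] <- stats::rexp(sum(hit), rate = 1 / (4 * base))
  })

  values <- round(pmax(baseline + bouts + spikes, 0))
  series <- count_series(values, epoch_seconds = ep * 60,
                         start_time = as.POSIXct("2020-01-06 00:00:00", tz = "UTC"),
                         subject_id = subject_id)
  structure(list(
    subject_id = subject_id, group = group, series = series,
    true_params = list(
      bout_rate = spec$bout_rate[[group]],
      bout_duration_mean = spec$bout_duration_mean[[group]],
      bout_duration_cv = spec$bout_duration_cv[[group]],
      realized_durations = durations)
  ), class = "subject_record")
}

#' Simulate a two-group actigraphy cohort
#'
#' Generates `n_per_group["N"]` non-depressed and `n_per_group["D"]`
#' depressed subjects. Per-subject seeds are derived deterministically from
#' the spec seed, so cohorts are reproducible while subjects remain
#' mutually independent.
#'
#' @param spec a [cohort_spec].
#' @return list of `subject_record`s (class `cohort`).
#' @export
gen_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("gen_cohort: spec must be a cohort_spec")
  if (any(spec$n_per_group == 0L)) {
    stop("gen_cohort: each group needs at least one subject")
  }
  recs <- list()
  idx <- 0L
  for (g in c("N", "D")) {
    for (i in seq_len(spec$n_per_group[[g]])) {
      idx <- idx + 1L
      id <- sprintf("%s%02d", g, i)
      recs[[id]] <- gen_subject(spec, g, id, seed = derive_seed(spec$seed, idx))
    }
  }
  structure(recs, class = "cohort")
}

#' Write a cohort to per-subject CSV files plus a manifest
#'
#' Each subject is written as `<subject_id>.csv` with columns
#' `subject_id,timestamp,counts` (ISO-8601 timestamps) and the group
#' labels as a tab-separated `manifest.tsv` (`subject_id`, `group`).
#'
#' @param cohort a `cohort` from [gen_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    subject_id = vapply(cohort, function(r) r$subject_id, character(1)),
    group = vapply(cohort, function(r) r$group, character(1)),
    stringsAsFactors = FALSE
  )
  for (rec in cohort) {
    s <- rec$series
    ts <- s$start_time + (seq_along(s$values) - 1) * s$epoch_seconds
    utils::write.csv(
      data.frame(subject_id = rec$subject_id,
                 timestamp = format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                 counts = s$values),
      file.path(dir, paste0(rec$subject_id, ".csv")),
      row.names = FALSE, quote = FALSE
    )
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
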