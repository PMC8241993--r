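#' Activity-count series
#'
#' Container for a regularly sampled activity-count time series, the raw
#' material of actigraphy analysis. Values are counts per epoch (typically
#' 1-minute epochs from a wrist-worn accelerometer); the container also
#' carries the sampling interval, an optional start timestamp and an
#' optional subject identifier.
#'
#' @param values numeric vector of counts (one per epoch).
#' @param epoch_seconds sampling interval in seconds (default 60).
#' @param start_time optional `POSIXct` timestamp of the first epoch.
#' @param subject_id optional subject identifier.
#' @param nonnegative enforce that all values are `>= 0` (the contract for
#'   real activity counts; simulated test fixtures such as noisy sines may
#'   set this to `FALSE`).
#' @return an object of class `count_series`.
#' @export
count_series <- function(values, epoch_seconds = 60, start_time = NULL,
                         subject_id = NA_character_, nonnegative = TRUE) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("count_series: 'values' must be nonempty")
  if (anyNA(values)) stop("count_series: 'values' must not contain NA")
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L ||
      epoch_seconds <= 0) {
    stop("count_series: 'epoch_seconds' must be a positive scalar")
  }
  if (nonnegative && any(values < 0)) {
    stop("count_series: negative counts are not allowed")
  }
  if (!is.null(start_time)) start_time <- as.POSIXct(start_time, tz = "UTC")
  structure(
    list(values = values, epoch_seconds = as.numeric(epoch_seconds),
         start_time = start_time, subject_id = subject_id),
    class = "count_series"
  )
}

#' @export
length.count_series <- function(x) length(x$values)

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %s: %d epochs of %gs (%.1f days)\n",
              ifelse(is.na(x$subject_id), "(unnamed)", x$subject_id),
              length(x$values), x$epoch_seconds,
              length(x$values) * x$epoch_seconds / 86400))
  cat(sprintf("  counts: mean %.2f, range [%g, %g]\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Rank-transformed series
#'
#' A time series whose values have been replaced by their midranks divided
#' by the series length, so the amplitude distribution is uniform on
#' (0, 1]. This is the input representation for recurrence analysis: it is
#' invariant under strictly increasing transforms of the raw counts and
#' immune to extreme activity spikes.
#'
#' @param values numeric vector in (0, 1] (midranks / N).
#' @return an object of class `rank_series` with fields `values` and `n`.
#' @seealso [rank_transform()]
#' @export
rank_series <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("rank_series: empty series")
  if (any(values <= 0 | values > 1)) {
    stop("rank_series: values must lie in (0, 1]")
  }
  structure(list(values = values, n = length(values)), class = "rank_series")
}

#' @export
length.rank_series <- function(x) x$n

#' @export
print.rank_series <- function(x, ...) {
  cat(sprintf("<rank_series> N = %d, values in (0, 1]\n", x$n))
  invisible(x)
}

# Condition helper: subject-level exclusions are signalled as typed errors
# so the pipeline can catch them and keep book.
exclusion_error <- function(reason, subject_id = NA_character_,
                            detail = NULL) {
  stop(structure(
    class = c("subject_exclusion", "error", "condition"),
    list(message = paste0("subject excluded: ", reason,
                          if (!is.null(detail)) paste0(" (", detail, ")")),
         call = sys.call(-1), reason = reason, subject_id = subject_id)
  ))
}

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state (all package randomness flows through explicit seeds).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-subject seed derivation, kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}
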