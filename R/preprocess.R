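#' Read a per-subject activity CSV
#'
#' Expects the column layout written by [write_cohort()]:
#' `subject_id,timestamp,counts` with ISO-8601 timestamps at a constant
#' cadence. The sampling interval is inferred from the first two
#' timestamps.
#'
#' @param path CSV file path.
#' @return a [count_series].
#' @export
read_subject_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "counts")
  if (!all(need %in% names(d))) {
    stop("read_subject_csv: expected columns ", paste(need, collapse = ", "))
  }
  ts <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) stop("read_subject_csv: unparseable timestamps in ", path)
  epoch <- if (nrow(d) > 1) as.numeric(difftime(ts[2], ts[1], units = "secs")) else 60
  count_series(d$counts, epoch_seconds = epoch, start_time = ts[1],
               subject_id = d$subject_id[1])
}

#' Read a headerless single-column counts file
#'
#' @param path text file with one count per line.
#' @param epoch_seconds sampling interval of the file.
#' @param subject_id optional identifier.
#' @return a [count_series].
#' @export
read_counts_file <- function(path, epoch_seconds = 60,
                             subject_id = NA_character_) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  count_series(v, epoch_seconds = epoch_seconds, subject_id = subject_id)
}

#' Trim leading/trailing non-wear periods
#'
#' Long runs of exactly-zero counts at the start or end of a recording are
#' taken to be non-wear (device not on the wrist) and removed. The rule is
#' deliberately mechanical — an ends-only maximal zero run of at least
#' `max_zero_run_minutes` is dropped — so the step is reproducible.
#' Interior zeros are never touched.
#'
#' @param series a [count_series].
#' @param max_zero_run_minutes minimum duration (minutes) of an end run of
#'   zeros for it to count as non-wear; default 180.
#' @return the trimmed [count_series].
#' @export
trim_nonwear <- function(series, max_zero_run_minutes = 180) {
  stopifnot(inherits(series, "count_series"))
  v <- series$values
  epd <- series$epoch_seconds / 60   # minutes per epoch
  thr <- max_zero_run_minutes / epd  # epochs
  nz <- which(v != 0)
  if (length(nz) == 0L) {
    exclusion_error("empty after non-wear trim", series$subject_id)
  }
  lead <- nz[1] - 1L
  trail <- length(v) - nz[length(nz)]
  from <- if (lead >= thr) nz[1] else 1L
  to <- if (trail >= thr) nz[length(nz)] else length(v)
  out <- series
  out$values <- v[from:to]
  if (!is.null(series$start_time)) {
    out$start_time <- series$start_time + (from - 1L) * series$epoch_seconds
  }
  out
}

#' Average counts into non-overlapping time bins
#'
#' Reduces a series to bin means over consecutive windows aligned to the
#' series start (default 10-minute bins, the standard resampling step
#' before recurrence analysis). An incomplete trailing window is dropped
#' rather than padded.
#'
#' @param series a [count_series].
#' @param bin_minutes bin width in minutes; must be a positive multiple of
#'   the sampling epoch.
#' @return a [count_series] of bin means with updated `epoch_seconds`.
#' @export
bin_series <- function(series, bin_minutes = 10) {
  stopifnot(inherits(series, "count_series"))
  per <- bin_minutes * 60 / series$epoch_seconds
  if (per < 1 || abs(per - round(per)) > 1e-9) {
    stop("bin_series: bin_minutes must be a positive multiple of the epoch")
  }
  per <- as.integer(round(per))
  nb <- length(series$values) %/% per
  if (nb == 0L) stop("bin_series: series shorter than one bin")
  kept <- series$values[seq_len(nb * per)]
  out <- series
  out$values <- as.numeric(colMeans(matrix(kept, nrow = per)))
  out$epoch_seconds <- bin_minutes * 60
  out
}

#' Harmonise series length
#'
#' Keeps the first `max_len` points of an over-long binned series so every
#' subject contributes the same amount of data; raises a typed
#' `subject_exclusion` error (reason `"insufficient data"`) when fewer than
#' `min_len` points remain.
#'
#' @param series a binned [count_series].
#' @param max_len maximum length kept (default 4000 points, ~28 days of
#'   10-minute bins).
#' @param min_len minimum admissible length (default 3000, ~21 days).
#' @return the (possibly truncated) [count_series].
#' @export
enforce_length <- function(series, max_len = 4000, min_len = 3000) {
  stopifnot(inherits(series, "count_series"))
  n <- length(series$values)
  if (n < min_len) {
    exclusion_error("insufficient data", series$subject_id,
                    sprintf("%d < %d points", n, min_len))
  }
  if (n > max_len) series$values <- series$values[seq_len(max_len)]
  series
}

#' Rank transform
#'
#' Replaces each value by its midrank divided by the series length `N`,
#' producing a series on (0, 1] with a uniform amplitude distribution.
#' Ties share their average rank, so identical counts remain exactly
#' recurrent after the transform. The result depends only on the ordering
#' of the input: any strictly increasing transform of the counts leaves it
#' unchanged.
#'
#' @param series a [count_series] or plain numeric vector.
#' @return a [rank_series].
#' @export
rank_transform <- function(series) {
  v <- if (inherits(series, "count_series")) series$values else as.numeric(series)
  if (length(v) == 0L) stop("rank_transform: empty series")
  rank_series(rank(v, ties.method = "average") / length(v))
}

#' Preprocess one subject for recurrence analysis
#'
#' Applies the full chain: non-wear trim, bin averaging, length
#' harmonisation, rank transform. Exclusions surface as typed
#' `subject_exclusion` errors.
#'
#' @param series raw [count_series].
#' @param config an [analysis_config()] (or a list with the same fields).
#' @return list with `trimmed` (pre-bin counts, used for circadian
#'   measures and mean activity), `binned`, and `ranks` (a [rank_series]).
#' @export
preprocess_series <- function(series, config = analysis_config()) {
  trimmed <- trim_nonwear(series, config$trim_zero_run_minutes)
  binned <- bin_series(trimmed, config$bin_minutes)
  binned <- enforce_length(binned, config$max_len, config$min_len)
  list(trimmed = trimmed, binned = binned, ranks = rank_transform(binned))
}
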