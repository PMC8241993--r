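#' Calibrate the recurrence threshold to a fixed recurrence rate
#'
#' Chooses the recurrence threshold `epsilon` as the smallest value in the
#' multiset of pairwise distances (self-pairs included) whose recurrence
#' rate reaches `target_rr`. The recurrence rate of a threshold is the
#' fraction of ordered pairs `(i, j)` — main diagonal included — with
#' `|x_i - x_j| <= epsilon`. Because the data are discrete the target can
#' rarely be hit exactly; the first crossing from below is returned
#' together with the achieved rate.
#'
#' When the tied pairs alone already meet the target (`RR(0) >=
#' target_rr`, e.g. long stretches of identical inactivity), the result
#' carries `clutter = TRUE` with `epsilon = 0`; see [check_clutter()] for
#' the exclusion rule built on this.
#'
#' The search is a bisection over the attained distance values using
#' two-pointer pair counting on the sorted series, O(N log N) — no N x N
#' structure is formed.
#'
#' @param x a [rank_series] (any numeric vector is accepted).
#' @param target_rr target recurrence rate (default 0.05).
#' @return list with `epsilon`, `rr` (achieved rate), `clutter` flag.
#' @export
calibrate_epsilon <- function(x, target_rr = 0.05) {
  v <- if (inherits(x, "rank_series")) x$values else as.numeric(x)
  n <- length(v)
  if (n < 2) stop("calibrate_epsilon: need at least 2 points")
  if (!(target_rr > 0 && target_rr < 1)) {
    stop("calibrate_epsilon: target_rr must be in (0, 1)")
  }
  xs <- sort(v)
  n2 <- as.double(n)^2
  need <- ceiling(target_rr * n2 - 1e-9)  # pair count needed for RR >= target

  if (cpp_count_pairs_le(xs, 0) >= need) {
    return(list(epsilon = 0,
                rr = cpp_count_pairs_le(xs, 0) / n2,
                clutter = TRUE))
  }
  lo <- 0
  hi <- xs[n] - xs[1]
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (cpp_count_pairs_le(xs, mid) >= need) hi <- mid else lo <- mid
    if (hi - lo < .Machine$double.eps * max(1, hi)) break
  }
  eps <- cpp_largest_distance_le(xs, hi)  # snap to an attained distance
  list(epsilon = eps, rr = cpp_count_pairs_le(xs, eps) / n2, clutter = FALSE)
}

#' Clutter exclusion check
#'
#' A series whose tied pairs alone meet the target recurrence rate cannot
#' be thresholded at that rate — the recurrence plot is cluttered by
#' blocks of identical values (typically long periods of inactivity) even
#' at `epsilon ~ 0`, and recurrence quantification is uninformative.
#' Such subjects are excluded.
#'
#' @param x a [rank_series] or numeric vector.
#' @param target_rr target recurrence rate (default 0.05).
#' @return list with `exclude` (logical), `rr0` (recurrence rate at
#'   `epsilon = 0`, i.e. the tied-pair fraction including self-pairs) and
#'   `reason`.
#' @export
check_clutter <- function(x, target_rr = 0.05) {
  v <- if (inherits(x, "rank_series")) x$values else as.numeric(x)
  n <- as.double(length(v))
  rr0 <- sum(as.double(table(v))^2) / n^2
  list(exclude = rr0 >= target_rr, rr0 = rr0,
       reason = if (rr0 >= target_rr) "cluttered recurrence plot" else NA_character_)
}

# Delay embedding: rows are the (m, tau) state vectors.
embed_series <- function(v, m, tau) {
  nv <- length(v) - (m - 1L) * tau
  if (nv < 2) stop("invalid embedding: fewer than 2 state vectors")
  sapply(seq_len(m), function(k) v[(1 + (k - 1) * tau):((k - 1) * tau + nv)])
}

#' Build a recurrence plot
#'
#' Constructs the symmetric binary recurrence matrix `R[i, j] = 1` iff the
#' states at times `i` and `j` lie within `epsilon` of each other. With the
#' default `embedding_dim = 1` the state is the (rank-transformed)
#' amplitude itself, so two time points recur when their amplitudes fall
#' within `epsilon`; for `embedding_dim > 1` delay vectors are compared
#' under the maximum norm. The main diagonal (line of identity) is always
#' all ones.
#'
#' This materialises the full N x N matrix and is meant for inspection,
#' plotting and moderate N; [rqa_measures()] on a series computes the same
#' quantifiers without building the matrix.
#'
#' @param x a [rank_series] or numeric vector.
#' @param epsilon recurrence threshold (>= 0), e.g. from
#'   [calibrate_epsilon()].
#' @param embedding_dim embedding dimension `m` (default 1).
#' @param delay embedding delay in samples (default 1).
#' @return an object of class `recurrence_plot`: fields `R` (logical
#'   matrix), `epsilon`, `rr` (achieved recurrence rate), `n`,
#'   `embedding_dim`, `delay`.
#' @export
recurrence_plot <- function(x, epsilon, embedding_dim = 1, delay = 1) {
  v <- if (inherits(x, "rank_series")) x$values else as.numeric(x)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    stop("recurrence_plot: epsilon must be a nonnegative scalar")
  }
  m <- as.integer(embedding_dim)
  tau <- as.integer(delay)
  if (m < 1 || tau < 1) stop("recurrence_plot: invalid embedding")
  # same floating-point slack as the compiled line counters, so the matrix
  # and matrix-free routes mark identical pairs on the rank lattice
  eps_fp <- epsilon + 1e-12
  if (m == 1L) {
    R <- abs(outer(v, v, "-")) <= eps_fp
  } else {
    E <- embed_series(v, m, tau)
    nv <- nrow(E)
    R <- matrix(TRUE, nv, nv)
    for (k in seq_len(m)) {
      R <- R & (abs(outer(E[, k], E[, k], "-")) <= eps_fp)
    }
  }
  structure(list(R = R, epsilon = epsilon, rr = mean(R), n = nrow(R),
                 embedding_dim = m, delay = tau),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("<recurrence_plot> N = %d, epsilon = %.5g, RR = %.4f (m = %d, tau = %d)\n",
              x$n, x$epsilon, x$rr, x$embedding_dim, x$delay))
  invisible(x)
}

as_rp_matrix <- function(rp) {
  if (inherits(rp, "recurrence_plot")) rp$R
  else if (is.matrix(rp)) rp != 0
  else stop("expected a recurrence_plot or a matrix")
}

line_distribution <- function(lengths, kind, min_length) {
  lengths <- lengths[lengths >= min_length]
  tab <- table(lengths)
  structure(list(lengths = as.integer(names(tab)),
                 counts = as.integer(tab),
                 kind = kind, min_length = min_length),
            class = "line_distribution")
}

#' Diagonal line-length distribution of a recurrence plot
#'
#' Histogram of maximal runs of recurrence points along all diagonals
#' parallel to the line of identity (LOI), in both triangles; the LOI
#' itself is excluded. Diagonal lines mark stretches where two parts of
#' the series show the same local evolution — the deterministic,
#' recurrent-pattern content of the signal.
#'
#' @param rp a `recurrence_plot` (or a binary matrix).
#' @param l_min minimum line length retained (default 2).
#' @return a `line_distribution` (fields `lengths`, `counts`).
#' @export
diagonal_lines <- function(rp, l_min = 2) {
  R <- as_rp_matrix(rp)
  n <- nrow(R)
  runs <- integer(0)
  for (d in seq_len(n - 1)) {
    i <- seq_len(n - d)
    for (vals in list(R[cbind(i, i + d)], R[cbind(i + d, i)])) {
      r <- rle(vals)
      runs <- c(runs, r$lengths[r$values])
    }
  }
  line_distribution(runs, "diagonal", l_min)
}

#' Vertical line-length distribution of a recurrence plot
#'
#' Histogram of maximal vertical runs of recurrence points over every
#' column of the full matrix (LOI points included). Vertical lines mark
#' periods of stasis: times during which the system lingers near the same
#' state.
#'
#' @param rp a `recurrence_plot` (or a binary matrix).
#' @param v_min minimum line length retained (default 2).
#' @return a `line_distribution`.
#' @export
vertical_lines <- function(rp, v_min = 2) {
  R <- as_rp_matrix(rp)
  runs <- integer(0)
  for (j in seq_len(ncol(R))) {
    r <- rle(R[, j])
    runs <- c(runs, r$lengths[r$values])
  }
  line_distribution(runs, "vertical", v_min)
}

# Shared quantifier arithmetic on full run-length histograms.
# diag_hist / vert_hist are counts indexed by length 1, 2, ...;
# n_total includes the LOI, n_offdiag does not.
measures_from_hists <- function(diag_hist, vert_hist, n_total, n_offdiag,
                                l_min = 2, v_min = 2) {
  stats_of <- function(hist, kmin) {
    len <- seq_along(hist)
    keep <- len >= kmin & hist > 0
    if (!any(keep)) {
      return(list(points = 0, nlines = 0, avg = 0, ent = 0))
    }
    l <- len[keep]; p <- hist[keep]
    nl <- sum(p)
    pr <- p / nl
    list(points = sum(l * p), nlines = nl,
         avg = sum(l * p) / nl, ent = -sum(pr * log(pr)))
  }
  dg <- stats_of(diag_hist, l_min)
  vt <- stats_of(vert_hist, v_min)
  det <- if (n_offdiag > 0) dg$points / n_offdiag else 0
  lam <- if (n_total > 0) vt$points / n_total else 0
  list(det = det, lam = lam,
       l_avg = dg$avg, l_ent = dg$ent, v_avg = vt$avg, v_ent = vt$ent,
       lam_det_ratio = if (det > 0) lam / det else NA_real_,
       det_zero = det == 0)
}

#' Recurrence quantification measures
#'
#' Computes the seven recurrence quantifiers from a series or a
#' pre-built recurrence plot:
#'
#' * `det` — determinism: recurrence points on diagonal lines of length
#'   `>= l_min` as a fraction of all off-LOI recurrence points;
#' * `lam` — laminarity: points on vertical lines of length `>= v_min` as
#'   a fraction of all recurrence points (LOI included);
#' * `l_avg`, `l_ent` — mean and Shannon entropy (natural log) of the
#'   diagonal line-length distribution: duration and diversity of
#'   recurrent activity patterns;
#' * `v_avg`, `v_ent` — the vertical-line analogues: duration and
#'   diversity of static (lingering) patterns;
#' * `lam_det_ratio` — `lam / det`, `NA` (with `det_zero = TRUE`) when no
#'   diagonal structure exists.
#'
#' Measures of an empty line distribution are 0. Given a series, the
#' computation runs in compiled code without materialising the matrix and
#' the threshold is calibrated with [calibrate_epsilon()] unless `epsilon`
#' is supplied.
#'
#' @param x a [rank_series], numeric vector, or `recurrence_plot`.
#' @param epsilon recurrence threshold; `NULL` (default) calibrates to
#'   `target_rr`. Ignored for a `recurrence_plot` input.
#' @param target_rr fixed recurrence rate for calibration (default 0.05).
#' @param l_min,v_min minimum diagonal / vertical line lengths (default 2).
#' @param embedding_dim,delay delay-embedding parameters (defaults 1, 1:
#'   amplitudes are compared directly).
#' @param theiler number of diagonals adjacent to the LOI to exclude from
#'   diagonal statistics (default 0: only the LOI itself is excluded).
#' @return an object of class `rqa_measures`: `rr`, `epsilon`, `det`,
#'   `lam`, `l_avg`, `l_ent`, `v_avg`, `v_ent`, `lam_det_ratio`, `n`,
#'   `clutter`, `det_zero`.
#' @export
rqa_measures <- function(x, epsilon = NULL, target_rr = 0.05,
                         l_min = 2, v_min = 2,
                         embedding_dim = 1, delay = 1, theiler = 0) {
  if (inherits(x, "recurrence_plot")) {
    R <- x$R
    n <- x$n
    dl <- diagonal_lines(x, l_min)
    vl <- vertical_lines(x, v_min)
    n_total <- sum(R)
    dh <- numeric(n); dh[dl$lengths] <- dl$counts
    vh <- numeric(n); vh[vl$lengths] <- vl$counts
    m <- measures_from_hists(dh, vh, n_total, n_total - n, l_min, v_min)
    out <- c(list(rr = x$rr, epsilon = x$epsilon, n = n, clutter = FALSE), m)
    class(out) <- "rqa_measures"
    return(out)
  }
  v <- if (inherits(x, "rank_series")) x$values else as.numeric(x)
  clutter <- FALSE
  if (is.null(epsilon)) {
    cal <- calibrate_epsilon(v, target_rr)
    epsilon <- cal$epsilon
    clutter <- cal$clutter
  }
  h <- cpp_rqa_histograms(v, epsilon, as.integer(embedding_dim),
                          as.integer(delay), as.integer(theiler))
  m <- measures_from_hists(h$diag_hist, h$vert_hist, h$n_total, h$n_offdiag,
                           l_min, v_min)
  out <- c(list(rr = h$n_total / as.double(h$n)^2, epsilon = epsilon,
                n = h$n, clutter = clutter), m)
  class(out) <- "rqa_measures"
  out
}

#' @export
print.rqa_measures <- function(x, ...) {
  cat(sprintf(paste0("<rqa_measures> N = %d, epsilon = %.5g, RR = %.4f\n",
                     "  DET = %.3f  LAM = %.3f  LAM/DET = %.3f\n",
                     "  L_avg = %.3f  L_ent = %.3f  V_avg = %.3f  V_ent = %.3f\n"),
              x$n, x$epsilon, x$rr, x$det, x$lam,
              ifelse(is.na(x$lam_det_ratio), NaN, x$lam_det_ratio),
              x$l_avg, x$l_ent, x$v_avg, x$v_ent))
  invisible(x)
}

#' @rdname rqa_measures
#' @param x an `rqa_measures` object.
#' @param ... unused.
#' @export
as.data.frame.rqa_measures <- function(x, ...) {
  data.frame(rr = x$rr, epsilon = x$epsilon, det = x$det, lam = x$lam,
             l_avg = x$l_avg, l_ent = x$l_ent, v_avg = x$v_avg,
             v_ent = x$v_ent, lam_det_ratio = x$lam_det_ratio)
}
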