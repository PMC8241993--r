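# Independent brute-force oracles used to validate the recurrence engine.
# These deliberately use the slowest, most literal formulation.

# Maximal-run histogram along every diagonal of `M` (both triangles,
# main diagonal excluded), runs of length >= lmin, as a named table.
oracle_diag_hist <- function(M, lmin = 2) {
  n <- nrow(M)
  runs <- integer(0)
  for (off in c(-(n - 1):-1, 1:(n - 1))) {
    vals <- logical(0)
    for (i in seq_len(n)) {
      j <- i + off
      if (j >= 1 && j <= n) vals <- c(vals, M[i, j] != 0)
    }
    run <- 0L
    for (v in c(vals, FALSE)) {
      if (v) run <- run + 1L
      else {
        if (run >= lmin) runs <- c(runs, run)
        run <- 0L
      }
    }
  }
  table(runs)
}

# Maximal vertical runs over every column of the full matrix.
oracle_vert_hist <- function(M, vmin = 2) {
  n <- nrow(M)
  runs <- integer(0)
  for (j in seq_len(n)) {
    run <- 0L
    for (v in c(M[, j] != 0, FALSE)) {
      if (v) run <- run + 1L
      else {
        if (run >= vmin) runs <- c(runs, run)
        run <- 0L
      }
    }
  }
  table(runs)
}

# Random symmetric binary matrix with an all-ones main diagonal.
random_sym_matrix <- function(n, p = 0.3) {
  M <- matrix(runif(n * n) < p, n, n)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- TRUE
  M
}

# Literal O(N^2) recurrence-rate curve: fraction of ordered pairs
# (self-pairs included) within eps.
oracle_rr <- function(v, eps) {
  mean(abs(outer(v, v, "-")) <= eps + 1e-12)
}

as_hist_table <- function(ld) {
  stats::setNames(as.integer(ld$counts), as.character(ld$lengths))
}

# Wrap a bare matrix as a recurrence_plot object for measure tests.
fake_rp <- function(M) {
  structure(list(R = M != 0, epsilon = NA_real_, rr = mean(M != 0),
                 n = nrow(M), embedding_dim = 1L, delay = 1L),
            class = "recurrence_plot")
}

make_series <- function(values, epoch_seconds = 60, ...) {
  count_series(values, epoch_seconds = epoch_seconds, ...)
}
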