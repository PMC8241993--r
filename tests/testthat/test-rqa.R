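test_that("threshold calibration finds the first crossing on the rank lattice", {
  # tie-free N = 4000: pairs within lag-101 rank distance number
  # 4000 + 2 * sum_{d=1}^{101} (4000 - d) = 801698, the first count >= 5%
  set.seed(10)
  x <- rank_transform(sample(4000))
  cal <- calibrate_epsilon(x, target_rr = 0.05)
  expect_equal(cal$epsilon, 101 / 4000, tolerance = 1e-10)
  expect_equal(cal$rr, 801698 / 16e6, tolerance = 1e-12)
  expect_false(cal$clutter)
})

test_that("tiny tie-free series is saturated by the LOI alone", {
  cal <- calibrate_epsilon(rank_transform(c(5, 1, 3, 2, 4)), target_rr = 0.05)
  expect_equal(cal$epsilon, 0)
  expect_equal(cal$rr, 5 / 25)
  expect_true(cal$clutter)
})

test_that("achieved rate is the first crossing: one candidate lower falls below target", {
  set.seed(21)
  for (n in c(50, 200, 1000)) {
    x <- rank_transform(rpois(n, 400))  # ties present but below the target
    cal <- calibrate_epsilon(x, target_rr = 0.05)
    expect_false(cal$clutter)
    expect_gte(cal$rr, 0.05)
    below <- cpp_count_pairs_le(sort(x$values), cal$epsilon - 1e-9) / n^2
    expect_lt(below, 0.05)
  }
})

test_that("recurrence rate is nondecreasing in epsilon", {
  set.seed(33)
  x <- rank_transform(rnorm(150))
  rrs <- vapply(seq(0, 1, by = 0.05),
                function(e) oracle_rr(x$values, e), numeric(1))
  expect_true(all(diff(rrs) >= 0))
})

test_that("recurrence matrix matches pairwise distances, symmetry and LOI", {
  x <- c(0.2, 0.4, 0.21, 0.8)
  rp <- recurrence_plot(x, 0.05)
  expected <- diag(4) > 0
  expected[1, 3] <- expected[3, 1] <- TRUE
  expect_equal(unname(rp$R), expected)

  set.seed(5)
  y <- rank_transform(rnorm(60))
  rp2 <- recurrence_plot(y, 0.1)
  expect_identical(rp2$R, t(rp2$R))
  expect_true(all(diag(rp2$R)))

  expect_equal(sum(recurrence_plot(y, 1)$R), 60 * 60)     # eps >= rank range
  expect_equal(unname(recurrence_plot(rank_transform(sample(30)), 0)$R),
               diag(30) > 0)                              # tie-free, eps = 0
})

test_that("diagonal line histogram matches hand-enumerated structures", {
  M <- diag(6) > 0
  for (k in 1:3) { M[k, k + 3] <- TRUE; M[k + 3, k] <- TRUE }
  dl <- diagonal_lines(M)
  expect_equal(as_hist_table(dl), c("3" = 2L))

  expect_length(diagonal_lines(diag(10))$lengths, 0)  # LOI excluded
})

test_that("vertical line histogram matches hand-enumerated structures", {
  expect_length(vertical_lines(diag(10))$lengths, 0)  # runs of length 1 only

  M <- diag(6) > 0
  M[2, 5] <- M[3, 5] <- M[5, 2] <- M[5, 3] <- TRUE
  vl <- vertical_lines(M)
  expect_equal(as_hist_table(vl), c("2" = 1L))

  allones <- matrix(TRUE, 7, 7)
  expect_equal(as_hist_table(vertical_lines(allones)), c("7" = 7L))
})

test_that("line extractors agree with naive scan oracles on random matrices", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    M <- random_sym_matrix(n, p = runif(1, 0.1, 0.6))
    expect_identical(as.vector(as_hist_table(diagonal_lines(M))),
                     as.vector(oracle_diag_hist(M)))
    expect_identical(as.vector(as_hist_table(vertical_lines(M))),
                     as.vector(oracle_vert_hist(M)))
  }
})

test_that("quantifiers evaluate hand-computed line distributions", {
  # LOI + three length-3 diagonal pairs: 6 off-LOI points, all on lines
  M <- diag(6) > 0
  for (k in 1:3) { M[k, k + 3] <- TRUE; M[k + 3, k] <- TRUE }
  m <- rqa_measures(fake_rp(M))
  expect_equal(m$det, 1)
  expect_equal(m$l_avg, 3)
  expect_equal(m$l_ent, 0)

  # diagonal histogram {2: 2, 3: 1}: L_ent = ln 3 - (2/3) ln 2, L_avg = 7/3
  M2 <- diag(10) > 0
  M2[cbind(1:3, 5:7)] <- TRUE            # run of 3 (upper)
  M2[cbind(1:2, 8:9)] <- TRUE            # run of 2 (upper)
  M2[cbind(5:6, 1:2)] <- TRUE            # run of 2 (lower)
  dl <- diagonal_lines(M2)
  expect_equal(as_hist_table(dl), c("2" = 2L, "3" = 1L))
  m2 <- rqa_measures(fake_rp(M2))
  expect_equal(m2$l_avg, 7 / 3)
  expect_equal(m2$l_ent, log(3) - (2 / 3) * log(2))
  expect_equal(m2$det, 1)                # all 7 off-LOI points on lines

  # all-ones matrix: LAM exact, DET/ratio in the large-N limit (corner
  # diagonals have length 1 and stay below l_min)
  m3 <- rqa_measures(fake_rp(matrix(TRUE, 50, 50)))
  expect_equal(m3$lam, 1)
  expect_gt(m3$det, 0.999)
  expect_equal(m3$lam_det_ratio, 1, tolerance = 1e-3)
})

test_that("empty line distributions give zero measures and flagged ratio", {
  m <- rqa_measures(fake_rp(diag(8)))
  expect_equal(m$det, 0)
  expect_equal(m$lam, 0)
  expect_equal(m$l_avg, 0)
  expect_equal(m$l_ent, 0)
  expect_true(m$det_zero)
  expect_true(is.na(m$lam_det_ratio))
})

test_that("matrix-free measures equal the matrix route, including embeddings", {
  set.seed(61)
  for (rep in 1:5) {
    x <- rank_transform(rpois(120, 15))
    cal <- calibrate_epsilon(x)
    for (m_dim in c(1, 2, 3)) {
      fast <- rqa_measures(x, epsilon = cal$epsilon, embedding_dim = m_dim,
                           delay = 2)
      slow <- rqa_measures(recurrence_plot(x, cal$epsilon,
                                           embedding_dim = m_dim, delay = 2))
      for (q in c("rr", "det", "lam", "l_avg", "l_ent", "v_avg", "v_ent",
                  "lam_det_ratio")) {
        expect_equal(fast[[q]], slow[[q]], tolerance = 1e-12,
                     label = paste(q, "m =", m_dim))
      }
    }
  }
})

test_that("embedded recurrence uses the maximum norm over delay vectors", {
  x <- c(0.1, 0.2, 0.35, 0.12, 0.22, 0.9)
  rp <- recurrence_plot(x, 0.05, embedding_dim = 2, delay = 1)
  nv <- 5
  expected <- matrix(FALSE, nv, nv)
  for (i in 1:nv) for (j in 1:nv) {
    expected[i, j] <- max(abs(x[i] - x[j]), abs(x[i + 1] - x[j + 1])) <= 0.05 + 1e-12
  }
  expect_equal(unname(rp$R), expected)
})

test_that("clutter check excludes inactivity-dominated series", {
  expect_true(check_clutter(rank_transform(rep(3, 50)))$exclude)
  expect_equal(check_clutter(rank_transform(rep(3, 50)))$rr0, 1)

  # 25% exactly-tied zeros, rest tie-free: tied fraction (250^2 + 750)/1000^2
  v <- c(rep(0, 250), seq_len(750))
  cl <- check_clutter(rank_transform(v))
  expect_equal(cl$rr0, (250^2 + 750) / 1e6)
  expect_true(cl$exclude)
  expect_equal(cl$rr0, oracle_rr(rank_transform(v)$values, 0))

  keep <- check_clutter(rank_transform(seq_len(100)))
  expect_false(keep$exclude)
  expect_equal(keep$rr0, 1 / 100)
})

test_that("rank-transformed periodic sawtooth is near-deterministic", {
  saw <- (0:3999) %% 100 + (0:3999) * 1e-6   # tie-free sawtooth, period 100
  x <- rank_transform(saw)
  cal <- calibrate_epsilon(x)
  m <- rqa_measures(x, epsilon = cal$epsilon)
  expect_gte(m$det, 0.95)
})
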