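test_that("Welch t from summaries reproduces published-style table rows", {
  # average activity row: n=25 mean=262.388 sd=77.570 vs n=21 mean=228.040 sd=84.319
  w <- welch_t(group_summary(n = 25, mean = 262.388, sd = 77.570),
               group_summary(n = 21, mean = 228.040, sd = 84.319))
  expect_equal(w$t, -1.427, tolerance = 5e-4)

  # diagonal-entropy row: n=25 mean=0.853 sd=0.210 vs n=21 mean=0.725 sd=0.202
  w2 <- welch_t(group_summary(n = 25, mean = 0.853, sd = 0.210),
                group_summary(n = 21, mean = 0.725, sd = 0.202))
  expect_equal(w2$t, -2.104, tolerance = 2e-3)   # printed to 3 decimals
  expect_true(w2$p < 0.05)

  same <- group_summary(n = 10, mean = 4, sd = 1)
  expect_equal(welch_t(same, same)$t, 0)
})

test_that("Welch t from raw samples agrees with stats::t.test and the summary route", {
  set.seed(121)
  for (rep in 1:10) {
    a <- rnorm(25, 10, 2)
    b <- rnorm(21, 9, 3)
    w <- welch_t(a, b)
    ref <- t.test(b, a, var.equal = FALSE)   # (D - N) convention
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
    w2 <- welch_t(group_summary(a), group_summary(b))
    expect_equal(w$t, w2$t)
  }
})

test_that("degenerate zero-variance comparisons are handled by convention", {
  z <- group_summary(n = 5, mean = 2, sd = 0)
  expect_equal(welch_t(z, z)$t, 0)
  inf <- welch_t(z, group_summary(n = 5, mean = 3, sd = 0))
  expect_true(is.infinite(inf$t) && inf$t > 0)
  expect_equal(inf$p, 0)
})

test_that("Cohen's d uses the pooled sample SD with the N-minus-D sign", {
  expect_equal(cohens_d(group_summary(n = 10, mean = 1, sd = 1),
                        group_summary(n = 10, mean = 0, sd = 1)), 1)
  expect_equal(cohens_d(group_summary(n = 8, mean = 3, sd = 2),
                        group_summary(n = 12, mean = 3, sd = 1)), 0)
  # pooled-SD evaluation of the diagonal-entropy row
  d <- cohens_d(group_summary(n = 25, mean = 0.853, sd = 0.210),
                group_summary(n = 21, mean = 0.725, sd = 0.202))
  expect_equal(d, 0.620, tolerance = 1e-3)
  expect_true(is.na(cohens_d(group_summary(n = 5, mean = 1, sd = 0),
                             group_summary(n = 5, mean = 2, sd = 0))))
})

test_that("swapping group labels flips t and d and preserves p", {
  set.seed(31)
  a <- group_summary(rnorm(20, 5, 2))
  b <- group_summary(rnorm(15, 6, 1))
  w <- welch_t(a, b); ws <- welch_t(b, a)
  expect_equal(w$t, -ws$t)
  expect_equal(w$p, ws$p)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
})

test_that("Spearman correlation handles monotone and anti-monotone inputs", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("Spearman rho is invariant under monotone transforms and matches cor.test", {
  set.seed(14)
  for (rep in 1:10) {
    x <- rnorm(30)
    y <- x + rnorm(30)
    r <- spearman_rho(x, y)
    expect_equal(r$rho, spearman_rho(exp(x), y)$rho)
    expect_equal(r$rho, spearman_rho(x, atan(y))$rho)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-10)
  }
})

test_that("logistic fit returns null pseudo-R2 for an uninformative feature", {
  set.seed(5)
  labels <- rep(c("N", "D"), each = 20)
  fit <- logistic_fit(data.frame(q = rnorm(40)), labels)
  expect_lt(fit$pseudo_r2, 0.08)
  expect_gte(fit$pseudo_r2, 0)
})

test_that("adding predictors never decreases the pseudo-R2", {
  set.seed(6)
  n <- 60
  x1 <- rnorm(n)
  labels <- ifelse(runif(n) < plogis(1.2 * x1), "D", "N")
  labels[1:2] <- "D"; labels[3:4] <- "N"    # guarantee both classes
  feats <- data.frame(x1 = x1, junk = rnorm(n))
  f1 <- logistic_fit(feats, labels, "x1")
  f2 <- logistic_fit(feats, labels, c("x1", "junk"))
  expect_gte(f2$pseudo_r2, f1$pseudo_r2 - 1e-10)
})

test_that("logistic fit recovers a known slope", {
  set.seed(7)
  n <- 500
  x <- rnorm(n)
  y <- ifelse(runif(n) < plogis(2 * x), "D", "N")
  fit <- logistic_fit(data.frame(x = x), factor(y, levels = c("N", "D")))
  expect_lt(abs(unname(fit$coefficients["x"]) - 2), 0.3)
  expect_false(fit$separation)
})

test_that("perfect separation is flagged, not silently reported", {
  x <- c(rnorm(15, -4), rnorm(15, 4))
  labels <- rep(c("N", "D"), each = 15)
  fit <- logistic_fit(data.frame(x = x), labels)
  expect_true(fit$separation)
  expect_true(fit$pseudo_r2 > 0.9)
})

test_that("group comparison table applies the sign convention and Bonferroni", {
  set.seed(20)
  tab <- data.frame(
    group = rep(c("N", "D"), c(25, 21)),
    lower_in_d = c(rnorm(25, 10, 1), rnorm(21, 5, 1)),
    equalish = rnorm(46)
  )
  res <- compare_groups(tab, c("lower_in_d", "equalish"))
  r1 <- res[res$quantifier == "lower_in_d", ]
  expect_lt(r1$t, 0)            # depressed mean lower -> negative t
  expect_gt(r1$d, 0)            # ... and positive d
  expect_true(r1$significant_raw && r1$significant_bonferroni)
  expect_equal(sign(r1$t), sign(r1$mean_D - r1$mean_N))

  # single quantifier: Bonferroni threshold equals the raw threshold
  res1 <- compare_groups(tab, "lower_in_d")
  expect_identical(res1$significant_raw, res1$significant_bonferroni)
})

test_that("entirely missing quantifier columns are skipped with a message", {
  tab <- data.frame(group = rep(c("N", "D"), each = 5),
                    ok = rnorm(10), broken = c(rep(NA_real_, 5), rnorm(5)))
  expect_message(res <- compare_groups(tab, c("ok", "broken")), "skipping")
  expect_equal(res$quantifier, "ok")
})
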