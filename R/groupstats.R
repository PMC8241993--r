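#' Group summary statistics
#'
#' @param x numeric vector (NAs dropped), or pass `n`, `mean`, `sd`
#'   directly to describe a group from printed summary statistics.
#' @param n,mean,sd explicit summary values (used when `x` is missing).
#' @return object of class `group_summary`: `n`, `mean`, `sd` (sample SD,
#'   denominator n - 1).
#' @export
group_summary <- function(x = NULL, n = NULL, mean = NULL, sd = NULL) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    n <- length(x)
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  if (is.null(n) || is.null(mean) || is.null(sd) || n < 2 || sd < 0) {
    stop("group_summary: need n >= 2, mean, sd >= 0")
  }
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Welch two-sample t-test from group summaries
#'
#' Welch's unequal-variance t-test computed from group summary statistics,
#' with Welch–Satterthwaite degrees of freedom and a two-sided p-value.
#' Sign convention: `a` is the reference (non-depressed) group and
#' `t = (mean_b - mean_a) / SE`, so a lower mean in group `b` gives a
#' negative t.
#'
#' @param a reference-group [group_summary()] (or numeric vector).
#' @param b comparison-group [group_summary()] (or numeric vector).
#' @return list: `t`, `df`, `p`. Both SDs zero with equal means gives
#'   `t = 0`; with unequal means, `t = +/-Inf` and `p = 0`.
#' @export
welch_t <- function(a, b) {
  if (!inherits(a, "group_summary")) a <- group_summary(a)
  if (!inherits(b, "group_summary")) b <- group_summary(b)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (va + vb == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(b$mean - a$mean) * Inf, df = NA_real_, p = 0))
  }
  t <- (b$mean - a$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cohen's d from group summaries
#'
#' Standardised mean difference with the pooled sample SD:
#' `d = (mean_a - mean_b) / s_pooled`,
#' `s_pooled = sqrt(((n_a - 1) sd_a^2 + (n_b - 1) sd_b^2) / (n_a + n_b - 2))`.
#' With `a` the non-depressed reference, d is positive when the reference
#' group has the higher mean (the opposite sign of the Welch t above, by
#' design, matching the reporting convention of case-control actigraphy
#' tables).
#'
#' @param a,b [group_summary()] objects (or numeric vectors).
#' @return Cohen's d (`NA` when the pooled SD is zero).
#' @export
cohens_d <- function(a, b) {
  if (!inherits(a, "group_summary")) a <- group_summary(a)
  if (!inherits(b, "group_summary")) b <- group_summary(b)
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 == 0) return(NA_real_)
  (a$mean - b$mean) / sqrt(sp2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a p-value from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`. Robust to
#' outliers and sensitive to any monotone (not just linear) association.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list: `rho`, `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("spearman_rho: need equal lengths >= 3")
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("spearman_rho: constant input")
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Logistic regression of group membership on quantifiers
#'
#' Maximum-likelihood logistic fit (with intercept) predicting the group
#' label from one or more quantifier columns, summarised by McFadden's
#' pseudo R-squared `1 - logLik(model) / logLik(null)`. Perfect
#' separation is detected (fitted probabilities indistinguishable from 0
#' or 1) and flagged; the pseudo R-squared is still reported.
#'
#' @param features data frame of per-subject predictor columns.
#' @param labels group labels (anything coercible to a 2-level factor;
#'   level order defines the modelled "success").
#' @param predictors columns of `features` to use (default: all).
#' @return object of class `logistic_result`: `predictors`,
#'   `coefficients`, `pseudo_r2`, `separation`, `converged`.
#' @export
logistic_fit <- function(features, labels, predictors = names(features)) {
  features <- as.data.frame(features)[, predictors, drop = FALSE]
  if (anyNA(features)) stop("logistic_fit: missing feature values")
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("logistic_fit: labels must have 2 levels")
  if (any(table(y) < 2)) stop("logistic_fit: need >= 2 subjects per class")
  d <- cbind(.y = as.integer(y) - 1L, features)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = d, family = stats::binomial())
  )
  null <- stats::glm(.y ~ 1, data = d, family = stats::binomial())
  pr2 <- 1 - as.numeric(stats::logLik(fit)) / as.numeric(stats::logLik(null))
  sep <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  structure(list(predictors = predictors,
                 coefficients = stats::coef(fit),
                 pseudo_r2 = max(0, pr2),
                 separation = sep, converged = fit$converged),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("<logistic_result> predictors: %s\n  McFadden pseudo-R2 = %.4f%s\n",
              paste(x$predictors, collapse = ", "), x$pseudo_r2,
              if (x$separation) " [perfect separation flagged]" else ""))
  invisible(x)
}

#' Per-quantifier group comparison table
#'
#' For each quantifier column, compares the two groups with Welch's t
#' (sign convention `D - N`) and Cohen's d (sign convention `N - D`),
#' and flags raw (`p < 0.05`) and Bonferroni-corrected
#' (`p < 0.05 / m_tests`) significance. Quantifier columns that are
#' entirely missing in either group are skipped with a message.
#'
#' @param table data frame of per-subject quantifiers plus a group column.
#' @param quantifiers names of the quantifier columns to compare.
#' @param group_col name of the group-label column (levels `"N"`, `"D"`).
#' @param m_tests number of tests for the Bonferroni threshold (default:
#'   the number of quantifiers compared).
#' @param alpha raw significance level (default 0.05).
#' @return data frame with one row per quantifier: group means/SDs, `t`,
#'   `df`, `p`, `d`, `significant_raw`, `significant_bonferroni`.
#' @export
compare_groups <- function(table, quantifiers, group_col = "group",
                           m_tests = length(quantifiers), alpha = 0.05) {
  g <- as.character(table[[group_col]])
  if (!all(g %in% c("N", "D"))) stop("compare_groups: groups must be 'N'/'D'")
  if (!any(g == "N") || !any(g == "D")) {
    stop("compare_groups: both groups must be nonempty")
  }
  rows <- lapply(quantifiers, function(q) {
    xn <- table[[q]][g == "N"]
    xd <- table[[q]][g == "D"]
    if (all(is.na(xn)) || all(is.na(xd))) {
      message("compare_groups: skipping '", q, "' (all missing in a group)")
      return(NULL)
    }
    sn <- group_summary(xn)
    sd_ <- group_summary(xd)
    w <- welch_t(sn, sd_)
    data.frame(quantifier = q,
               n_N = sn$n, mean_N = sn$mean, sd_N = sn$sd,
               n_D = sd_$n, mean_D = sd_$mean, sd_D = sd_$sd,
               t = w$t, df = w$df, p = w$p, d = cohens_d(sn, sd_),
               significant_raw = w$p < alpha,
               significant_bonferroni = w$p < alpha / m_tests)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
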