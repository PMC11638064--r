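#' Ordinary least squares on risk-allele dosage
#'
#' Fits `y = alpha + beta * g` by closed-form OLS, the regression used to
#' relate normalized intron coverage or enzyme activity to risk-allele
#' dosage. The two-sided p-value comes from the t distribution with
#' `n - 2` degrees of freedom; `r2` is the unadjusted coefficient of
#' determination.
#'
#' Degenerate cases follow the conventions used throughout the package:
#' a constant outcome gives `slope = 0`, `r2 = 0` and `p = 1`; a perfect
#' fit with non-zero slope gives `se = 0` and `p = 0`.
#'
#' @param y Numeric outcome vector (coverage, activity, ...).
#' @param g Numeric predictor, typically risk-allele dosage in `{0, 1, 2}`
#'   or a binary group indicator.
#' @param grouping Label recorded on the fit, `"dosage"` or `"binary"`.
#' @return An object of class `dosage_fit`; see [tidy.dosage_fit()].
#' @examples
#' fit <- ols_dosage(c(1, 2, 3), c(0, 1, 2))
#' tidy(fit)
#' @export
ols_dosage <- function(y, g, grouping = "dosage") {
  y <- as.numeric(y)
  g <- as.numeric(g)
  stopifnot(length(y) == length(g))
  keep <- is.finite(y) & is.finite(g)
  y <- y[keep]
  g <- g[keep]
  n <- length(y)
  if (n < 3) abort("ols_dosage() needs at least 3 complete observations")
  sxx <- sum((g - mean(g))^2)
  if (sxx == 0) abort("no contrast: predictor has zero variance")

  sxy <- sum((g - mean(g)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  beta <- sxy / sxx
  alpha <- mean(y) - beta * mean(g)
  rss <- syy - beta * sxy
  rss <- max(rss, 0)
  df <- n - 2L
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)

  if (syy == 0) {
    # constant outcome: no evidence of association by convention
    beta <- 0
    se <- 0
    tval <- 0
    p <- 1
    r2 <- 0
  } else if (se == 0) {
    tval <- sign(beta) * Inf
    p <- if (beta == 0) 1 else 0
    r2 <- 1
  } else {
    tval <- beta / se
    p <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
    r2 <- 1 - rss / syy
  }

  structure(
    list(
      slope = beta, intercept = alpha, se = se, t = tval, p = p,
      r2 = r2, n = n, df = df, grouping = grouping,
      data = tibble(y = y, g = g)
    ),
    class = "dosage_fit"
  )
}

#' @export
print.dosage_fit <- function(x, ...) {
  cat(sprintf(
    "Dosage regression (%s grouping, n = %d)\n  beta = %.4g (se = %.4g), t = %.3g, p = %.3g, r2 = %.3g\n",
    x$grouping, x$n, x$slope, x$se, x$t, x$p, x$r2
  ))
  invisible(x)
}

#' @describeIn ols_dosage Coefficient-level summary as a tibble.
#' @param x A `dosage_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dosage_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "dosage"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se),
    statistic = c(NA_real_, x$t),
    p.value = c(NA_real_, x$p)
  )
}

#' @describeIn ols_dosage One-row model summary as a tibble.
#' @exportS3Method generics::glance
glance.dosage_fit <- function(x, ...) {
  tibble(
    r.squared = x$r2, statistic = x$t, p.value = x$p,
    df.residual = x$df, nobs = x$n, grouping = x$grouping
  )
}

#' Directional two-group comparison
#'
#' Two-group OLS on an indicator predictor (group B vs group A), reported
#' with a one-sided p-value: half the two-sided p when the estimated
#' difference lies in the stated direction, otherwise one minus that half.
#' This is numerically identical to the pooled-variance two-sample t-test.
#'
#' @param group_a,group_b Numeric vectors of measurements.
#' @param direction `"less"` if group B is expected below group A,
#'   `"greater"` for the opposite.
#' @return A tibble with `beta` (mean B minus mean A), `se`, `t`,
#'   `p_one_sided`, `p_two_sided` and group sizes.
#' @export
one_sided_pair_test <- function(group_a, group_b, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2) abort("both groups need n >= 2")
  y <- c(a, b)
  g <- c(rep(0, length(a)), rep(1, length(b)))
  if (var(y) == 0) abort("degenerate variance: all values identical")
  fit <- ols_dosage(y, g, grouping = "binary")
  half <- fit$p / 2
  sign_ok <- if (direction == "less") fit$slope <= 0 else fit$slope >= 0
  p1 <- if (fit$slope == 0) 0.5 else if (sign_ok) half else 1 - half
  tibble(
    beta = fit$slope, se = fit$se, t = fit$t,
    p_one_sided = p1, p_two_sided = fit$p,
    n_a = length(a), n_b = length(b), direction = direction
  )
}

#' Exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test with both margins fixed: the two-sided
#' p-value is the sum of probabilities of all tables at least as extreme
#' (probability no larger than the observed table). The odds ratio is the
#' sample cross-product ratio, not the conditional MLE.
#'
#' @param tab A 2x2 matrix of non-negative integer counts (rows: groups,
#'   columns: outcome yes/no).
#' @return A tibble with `odds_ratio`, `p`, and `defined` (FALSE when a
#'   margin is all zero, in which case `p` is `NA`).
#' @examples
#' fisher_2x2(matrix(c(10, 0, 0, 10), nrow = 2))
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("fisher_2x2() needs non-negative integer cells")
  }
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(tibble(odds_ratio = NA_real_, p = NA_real_, defined = FALSE))
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  k <- max(0, r1 - c2):min(r1, c1)
  probs <- dhyper(k, c1, c2, r1)
  p_obs <- dhyper(tab[1, 1], c1, c2, r1)
  # relative tolerance guards against ties lost to floating point
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  tibble(odds_ratio = or, p = min(p, 1), defined = TRUE)
}

#' Clopper-Pearson binomial confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}
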