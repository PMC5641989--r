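# Method-agreement and power statistics for paired PWV / area measurements.

#' Bland-Altman agreement of two paired measurement series
#'
#' Differences are `y - x`; the bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96 * SD` (sample SD, n - 1 denominator).
#'
#' @param x,y paired measurements (equal length >= 3)
#' @return list with `bias`, `loa` (lower, upper), `sd_diff`, `n`
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 pairs are required")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       sd_diff = s, n = length(d))
}

#' Regression concordance of two paired measurement series
#'
#' Ordinary least squares of `y` on `x` with Pearson correlation and the
#' 95% confidence interval of the slope from the t-quantile at n - 2
#' degrees of freedom.
#'
#' @param x,y paired measurements (n >= 3, `var(x) > 0`)
#' @return list with `slope`, `intercept`, `pearson_r`, `slope_ci95`, `n`
#' @export
regression_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("at least 3 pairs are required")
  if (stats::var(x) == 0) stop("x has zero variance; slope undefined")
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = 0.95)
  r <- stats::cor(x, y)
  list(slope = unname(stats::coef(fit)["x"]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = r, slope_ci95 = unname(c(ci)), n = n)
}

#' Paired two-tailed Student's t-test
#'
#' Zero-variance differences leave the statistic undefined; such input is
#' reported as degenerate rather than an error.
#'
#' @param x,y paired measurements (n >= 2)
#' @return list with `t_stat`, `p_value`, `df`, `mean_diff`, `degenerate`
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("at least 2 pairs are required")
  d <- y - x
  if (stats::sd(d) == 0) {
    return(list(t_stat = NA_real_, p_value = NA_real_, df = n - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(y, x, paired = TRUE)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Sample size for a paired two-tailed t-test
#'
#' Smallest number of pairs n whose noncentral-t power reaches the target:
#' at n - 1 degrees of freedom and noncentrality `sqrt(n) * delta_mu /
#' sigma`, the probability of |t| exceeding the two-tailed critical value
#' must be at least `power`. With an expected difference of 0.5 m/s, a
#' difference SD of 0.5 m/s, alpha 0.05 and power 0.8 this yields n = 10.
#'
#' @param delta_mu expected mean difference (> 0)
#' @param sigma standard deviation of the paired differences (> 0)
#' @param alpha two-tailed significance level
#' @param power target power
#' @param n_max search limit
#' @return the required number of pairs (integer)
#' @export
sample_size_paired_t <- function(delta_mu, sigma, alpha = 0.05, power = 0.8,
                                 n_max = 1e6L) {
  if (delta_mu <= 0 || sigma <= 0) stop("delta_mu and sigma must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  d <- delta_mu / sigma
  for (n in 2:n_max) {
    tc <- stats::qt(1 - alpha / 2, df = n - 1)
    ncp <- sqrt(n) * d
    pw <- stats::pt(tc, df = n - 1, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, df = n - 1, ncp = ncp)
    if (pw >= power) return(as.integer(n))
  }
  stop("target power not reachable within n_max pairs")
}
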