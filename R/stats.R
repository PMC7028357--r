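# The treatment-comparison battery: one-tailed Welch t-tests, linear-model
# R-squared with treatment as a fixed factor, the exact conditional
# two-sample Poisson rate test, Bonett's kurtosis-adjusted variance test,
# two-sample Kolmogorov-Smirnov tests, and variance-change factors.

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom, wrapping
#' [stats::t.test()].
#'
#' @param x,y Numeric samples (each `n >= 2`, with nonzero variance in at
#'   least one).
#' @param tail `"greater"` (mean of `x` exceeds mean of `y`), `"less"`, or
#'   `"two_sided"`.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y, tail = c("greater", "less", "two_sided")) {
  tail <- match.arg(tail)
  if (length(x) < 2L || length(y) < 2L) stop_domain("each sample needs n >= 2")
  if (var(x) == 0 && var(y) == 0) stop_domain("both samples have zero variance")
  ht <- t.test(x, y, var.equal = FALSE,
               alternative = switch(tail, two_sided = "two.sided", tail))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Treatment R-squared from a binary-factor linear model
#'
#' For a Gaussian linear model with one binary factor, the fraction of
#' variance explained is `SS_between / SS_total`; the p-value comes from the
#' F test with (1, n - 2) degrees of freedom.
#'
#' @param values Per-sample trait values.
#' @param treatment Per-sample group labels (exactly 2 levels present).
#' @return List with `r2`, `p`.
#' @export
glm_r2 <- function(values, treatment) {
  treatment <- as.factor(as.character(treatment))
  if (nlevels(treatment) != 2L) stop_domain("need exactly 2 treatment levels")
  if (var(values) == 0) stop_domain("zero total variance")
  fit <- lm(values ~ treatment)
  # perfect group separation is a legitimate corner (R^2 = 1); silence lm's
  # "essentially perfect fit" note
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  f <- sm$fstatistic
  p <- if (is.null(f)) NA_real_ else unname(pf(f[1], f[2], f[3], lower.tail = FALSE))
  list(r2 = r2, p = p)
}

#' Exact conditional two-sample Poisson rate test
#'
#' Tests equality of two Poisson rates from counts `x1`, `x2` observed over
#' exposures `t1`, `t2`.  Conditional on the total `m = x1 + x2`, `X1` is
#' Binomial(`m`, `t1/(t1+t2)`) under the null, which gives an exact
#' binomial-tail p-value (the classical conditional construction; only the
#' exposure ratio matters).  `tail = "greater"` returns `P(X >= x1)` for a
#' rate in group 1 exceeding that in group 2; `"two_sided"` doubles the
#' smaller tail (capped at 1).
#'
#' @param x1,x2 Non-negative counts (`x1 + x2 >= 1`).
#' @param t1,t2 Positive exposures (e.g. samples times mean reads).
#' @param tail `"greater"`, `"less"`, or `"two_sided"`.
#' @return The p-value.
#' @export
poisson_rate_test <- function(x1, t1, x2, t2, tail = c("greater", "less", "two_sided")) {
  tail <- match.arg(tail)
  stopifnot(t1 > 0, t2 > 0, x1 >= 0, x2 >= 0)
  m <- x1 + x2
  if (m < 1) stop_domain("both counts are zero")
  pi0 <- t1 / (t1 + t2)
  p_ge <- pbinom(x1 - 1, m, pi0, lower.tail = FALSE) # P(X >= x1)
  p_le <- pbinom(x1, m, pi0)                         # P(X <= x1)
  switch(tail,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# trimmed mean with Bonett's trim proportion 1/(2*sqrt(n-4)), floored at 0
# for n <= 4 and capped at the median
.bonett_trim_mean <- function(x) {
  n <- length(x)
  tr <- if (n > 4L) 1 / (2 * sqrt(n - 4)) else 0
  mean(x, trim = min(tr, 0.5))
}

#' Bonett's two-sample test for equality of variances
#'
#' The kurtosis-adjusted procedure for `ln(s1^2 / s2^2)`.  The pooled
#' kurtosis is estimated from fourth-power deviations about trimmed means
#' (trim proportion `1/(2*sqrt(n-4))`, floored at 0 for `n <= 4`):
#'
#'   `kurt = (n1 + n2) * (sum((x-m1)^4) + sum((y-m2)^4)) /
#'           (sum((x-xbar)^2) + sum((y-ybar)^2))^2`
#'
#' giving the standard error
#'
#'   `se^2 = (kurt - (n1-3)/n1)/(n1-1) + (kurt - (n2-3)/n2)/(n2-1)`.
#'
#' The test statistic shifts the log variance ratio by the small-sample
#' adjustment constant `c = (n1/(n1 - 1.96)) / (n2/(n2 - 1.96))` (the
#' published adjustment evaluated at the conventional two-sided 5% normal
#' critical value; it equals 1 for equal sample sizes) and refers it to the
#' normal distribution:
#'
#'   `z = ln(c * s1^2 / s2^2) / se`,  two-sided p from the normal reference.
#'
#' @param x,y Numeric samples, each `n >= 3` with positive variance.
#' @return List with `z`, `p` (two-sided).
#' @export
bonett_var_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3L || n2 < 3L) stop_domain("each sample needs n >= 3")
  s1 <- var(x); s2 <- var(y)
  if (s1 == 0 || s2 == 0) stop_domain("zero variance in a sample")
  m1 <- .bonett_trim_mean(x); m2 <- .bonett_trim_mean(y)
  num <- sum((x - m1)^4) + sum((y - m2)^4)
  den <- (sum((x - mean(x))^2) + sum((y - mean(y))^2))^2
  kurt <- (n1 + n2) * num / den
  se <- sqrt((kurt - (n1 - 3) / n1) / (n1 - 1) +
             (kurt - (n2 - 3) / n2) / (n2 - 1))
  cc <- (n1 / (n1 - 1.96)) / (n2 / (n2 - 1.96))
  z <- log(cc * s1 / s2) / se
  list(z = unname(z), p = unname(2 * pnorm(-abs(z))))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs.  The p-value
#' is exact (full distribution of D under the permutation null) when
#' `n * m <= 10^4` and asymptotic otherwise.
#'
#' @param x,y Numeric samples (each `n >= 1`).
#' @return List with `D`, `p`, and `exact` (logical).
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop_domain("empty sample")
  use_exact <- (as.double(length(x)) * length(y)) <= 1e4
  ht <- suppressWarnings(ks.test(x, y, exact = use_exact))
  list(D = unname(ht$statistic), p = unname(ht$p.value), exact = use_exact)
}

#' Variance-change factor between two samples
#'
#' Ratio of unbiased sample variances `var(x) / var(y)`; e.g. with `x` the
#' unfertilized and `y` the fertilized sample, a factor of 8 means the
#' variance decreased 8-fold under fertilization.
#'
#' @param x,y Numeric samples; `var(y)` must be positive.
#' @return The variance ratio.
#' @export
variance_change <- function(x, y) {
  if (var(y) == 0) stop_domain("zero variance in the reference sample")
  var(x) / var(y)
}
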