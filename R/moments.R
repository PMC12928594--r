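# Single-group estimators: small-sample-corrected skewness and excess
# kurtosis, Pearson correlation, Fisher's z, and their analytic sampling
# variances.

check_sample <- function(x, min_n, what) {
  if (!is.numeric(x)) invalid_input(sprintf("%s requires a numeric sample", what))
  if (anyNA(x)) invalid_input(sprintf("%s: sample contains missing values; drop them upstream", what))
  if (any(!is.finite(x))) invalid_input(sprintf("%s: sample contains non-finite values", what))
  n <- length(x)
  if (n < min_n) {
    invalid_input(sprintf("%s requires at least %d observations, got %d", what, min_n, n))
  }
  x
}

#' Small-sample-corrected sample skewness
#'
#' The adjusted Fisher--Pearson standardized third moment: the plug-in
#' coefficient \eqn{g_1 = m_3 / m_2^{3/2}} (central moments with divisor
#' \eqn{n}) multiplied by \eqn{\sqrt{n(n-1)}/(n-2)}. Zero for symmetric
#' samples; positive values indicate an elongated right tail.
#'
#' @param x Numeric vector, at least 3 observations, not all identical.
#' @return The skewness estimate (unitless scalar).
#' @examples
#' sample_skewness(c(0, 0, 0, 1)) # 2
#' @seealso [skewness_sampling_variance()], [delta_skewness()]
#' @export
sample_skewness <- function(x) {
  x <- check_sample(x, 3L, "skewness")
  n <- length(x)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 <= 0) undefined_statistic("skewness undefined: zero variance (all values identical)")
  (mean(d^3) / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

#' Analytic sampling variance of sample skewness
#'
#' Normal-theory variance \eqn{6n(n-1)/[(n-2)(n+1)(n+3)]}; approaches
#' \eqn{6/n} for large samples.
#'
#' @param n Integer sample size(s), each at least 3. Vectorized.
#' @return Sampling variance(s) of the skewness estimator.
#' @examples
#' skewness_sampling_variance(10)
#' @export
skewness_sampling_variance <- function(n) {
  if (!is.numeric(n) || anyNA(n) || any(n < 3) || any(n != floor(n))) {
    invalid_input("skewness sampling variance requires integer n >= 3")
  }
  6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3))
}

#' Small-sample-corrected sample excess kurtosis
#'
#' The standard unbiased-under-normality G2 estimator,
#' \deqn{\frac{(n-1)}{(n-2)(n-3)}\left[(n+1)\,g_2 + 6\right],}
#' with \eqn{g_2 = m_4/m_2^2 - 3}. Expectation 0 for normal populations
#' (kurtosis 3 on the non-excess scale); positive values indicate heavier
#' tails than the normal.
#'
#' @param x Numeric vector, at least 4 observations, not all identical.
#' @return The excess kurtosis estimate (unitless scalar).
#' @examples
#' sample_excess_kurtosis(c(0, 0, 1, 1)) # -6
#' @seealso [kurtosis_sampling_variance()], [delta_kurtosis()]
#' @export
sample_excess_kurtosis <- function(x) {
  x <- check_sample(x, 4L, "excess kurtosis")
  n <- length(x)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 <= 0) undefined_statistic("kurtosis undefined: zero variance (all values identical)")
  g2 <- mean(d^4) / m2^2 - 3
  ((n - 1) / ((n - 2) * (n - 3))) * ((n + 1) * g2 + 6)
}

#' Analytic sampling variance of sample excess kurtosis
#'
#' Normal-theory variance \eqn{24n(n-1)^2/[(n-3)(n-2)(n+3)(n+5)]};
#' approaches \eqn{24/n} for large samples.
#'
#' @param n Integer sample size(s), each at least 4. Vectorized.
#' @return Sampling variance(s) of the excess kurtosis estimator.
#' @examples
#' kurtosis_sampling_variance(10)
#' @export
kurtosis_sampling_variance <- function(n) {
  if (!is.numeric(n) || anyNA(n) || any(n < 4) || any(n != floor(n))) {
    invalid_input("kurtosis sampling variance requires integer n >= 4")
  }
  24 * n * (n - 1)^2 / ((n - 3) * (n - 2) * (n + 3) * (n + 5))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] adding the typed input checks the rest of
#' the pipeline relies on (paired lengths, minimum n, non-constant inputs).
#'
#' @param x,y Paired numeric vectors of equal length, at least 4 pairs.
#' @return Correlation coefficient in \eqn{[-1, 1]}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    invalid_input(sprintf("paired samples of unequal length (%d vs %d)", length(x), length(y)))
  }
  x <- check_sample(x, 4L, "correlation")
  y <- check_sample(y, 4L, "correlation")
  if (stats::var(x) <= 0 || stats::var(y) <= 0) {
    undefined_statistic("correlation undefined: at least one variable is constant")
  }
  stats::cor(x, y)
}

#' Fisher's z transform and its inverse
#'
#' \eqn{z = \tfrac{1}{2}\ln\{(1+r)/(1-r)\}} (equivalently \eqn{\mathrm{atanh}(r)}),
#' the variance-stabilizing transform of Pearson's r.
#'
#' @param r Correlation value(s) with \eqn{|r| < 1}.
#' @return Transformed value(s).
#' @examples
#' fisher_z(0.5)
#' fisher_z_inverse(fisher_z(0.5))
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r) || anyNA(r)) invalid_input("fisher_z requires numeric r")
  if (any(abs(r) >= 1)) {
    domain_error("|r| >= 1: Fisher's z is infinite at perfect correlation")
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-z value(s).
#' @export
fisher_z_inverse <- function(z) {
  if (!is.numeric(z) || anyNA(z)) invalid_input("fisher_z_inverse requires numeric z")
  tanh(z)
}

#' Sampling variance of Fisher's z
#'
#' \eqn{1/(n-3)} under bivariate normality.
#'
#' @param n Integer sample size(s), each at least 4. Vectorized.
#' @return Sampling variance(s).
#' @export
fisher_z_variance <- function(n) {
  if (!is.numeric(n) || anyNA(n) || any(n < 4) || any(n != floor(n))) {
    invalid_input("Fisher z sampling variance requires integer n >= 4")
  }
  1 / (n - 3)
}
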