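# Leave-one-out (delete-1) jackknife: Tukey (n-1)/n variance scaling and the
# usual bias-corrected point estimate n*theta_hat - (n-1)*mean(theta_(i)).

jackknife_result <- function(plug_in, loo, n) {
  loo_bar <- mean(loo)
  flag <- FALSE
  # diagnostic: strongly asymmetric leave-one-out distributions signal the
  # interval-coverage failures seen for kurtosis contrasts
  if (length(unique(loo)) > 2) {
    sk <- tryCatch(sample_skewness(loo), momentdiff_error = function(e) NA_real_)
    flag <- isTRUE(abs(sk) > 2)
  }
  structure(
    list(
      plug_in = plug_in,
      bias_corrected = n * plug_in - (n - 1) * loo_bar,
      variance = (n - 1) / n * sum((loo - loo_bar)^2),
      n = n,
      pseudovalue_skew_flag = flag
    ),
    class = "jackknife_result"
  )
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf(
    "Jackknife (n = %d): plug-in %.6g, bias-corrected %.6g, variance %.6g%s\n",
    x$n, x$plug_in, x$bias_corrected, x$variance,
    if (x$pseudovalue_skew_flag) " [skewed leave-one-out distribution]" else ""
  ))
  invisible(x)
}

#' Delete-1 jackknife of an arbitrary statistic
#'
#' Recomputes `statistic` on each of the n leave-one-out subsamples and
#' returns the jackknife variance \eqn{(n-1)/n \sum_i (\theta_{(i)} -
#' \bar\theta_{(\cdot)})^2} together with the bias-corrected point estimate
#' \eqn{n\hat\theta - (n-1)\bar\theta_{(\cdot)}}. For the sample mean the
#' variance equals \eqn{s^2/n} exactly and the bias correction is a no-op;
#' both identities are used as correctness oracles in the test suite.
#'
#' @param statistic Function of a numeric vector returning a scalar.
#' @param x Numeric vector; every leave-one-out subsample must be a valid
#'   input for `statistic`.
#' @param ... Further arguments passed to `statistic`.
#' @return A `jackknife_result`: list with elements `plug_in`,
#'   `bias_corrected`, `variance`, `n`, and `pseudovalue_skew_flag` (TRUE when
#'   the leave-one-out estimates are strongly asymmetric, |skewness| > 2).
#' @examples
#' jackknife(mean, rnorm(20))
#' @export
jackknife <- function(statistic, x, ...) {
  n <- length(x)
  if (n < 2) invalid_input("jackknife requires at least 2 observations")
  plug_in <- statistic(x, ...)
  loo <- vapply(seq_len(n), function(i) {
    tryCatch(
      statistic(x[-i], ...),
      error = function(e) {
        md_stop(
          "momentdiff_invalid_input",
          sprintf("statistic undefined on leave-one-out subsample %d: %s", i, conditionMessage(e))
        )
      }
    )
  }, numeric(1))
  jackknife_result(plug_in, loo, n)
}

# Fast vectorized leave-one-out path for the moment statistics. Centers the
# data first (both statistics are location invariant) and updates power sums;
# agrees with the naive jackknife() to 1e-10 (tested).
jackknife_moments <- function(x, kind = c("skewness", "kurtosis")) {
  kind <- match.arg(kind)
  min_n <- if (kind == "skewness") 4L else 5L # statistic minimum + 1
  x <- check_sample(x, min_n, sprintf("jackknife %s", kind))
  n <- length(x)
  y <- x - mean(x)
  s1 <- sum(y) - y
  s2 <- sum(y^2) - y^2
  s3 <- sum(y^3) - y^3
  s4 <- sum(y^4) - y^4
  m <- n - 1
  mu <- s1 / m
  m2 <- s2 / m - mu^2
  if (any(m2 <= 0)) {
    undefined_statistic(sprintf(
      "%s undefined on leave-one-out subsample %d (zero variance)",
      kind, which(m2 <= 0)[1]
    ))
  }
  if (kind == "skewness") {
    plug_in <- sample_skewness(x)
    m3 <- s3 / m - 3 * mu * s2 / m + 2 * mu^3
    loo <- (m3 / m2^1.5) * sqrt(m * (m - 1)) / (m - 2)
  } else {
    plug_in <- sample_excess_kurtosis(x)
    m4 <- s4 / m - 4 * mu * s3 / m + 6 * mu^2 * s2 / m - 3 * mu^4
    g2 <- m4 / m2^2 - 3
    loo <- ((m - 1) / ((m - 2) * (m - 3))) * ((m + 1) * g2 + 6)
  }
  jackknife_result(plug_in, loo, n)
}

#' Leave-one-pair-out jackknife of Fisher's z
#'
#' Drops one (x, y) pair at a time, recomputes Pearson's r on the remaining
#' pairs, applies Fisher's z per subsample, and returns the jackknife variance
#' and bias-corrected z. Row order does not affect the result.
#'
#' @param x,y Paired numeric vectors, at least 5 pairs.
#' @return A `jackknife_result` for the Fisher-z statistic.
#' @export
jackknife_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    invalid_input(sprintf("paired samples of unequal length (%d vs %d)", length(x), length(y)))
  }
  x <- check_sample(x, 5L, "jackknife correlation")
  y <- check_sample(y, 5L, "jackknife correlation")
  n <- length(x)
  r_full <- pearson_correlation(x, y)
  if (abs(r_full) >= 1) domain_error("|r| = 1: Fisher's z undefined")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc) - xc
  sy <- sum(yc) - yc
  sxx <- sum(xc^2) - xc^2
  syy <- sum(yc^2) - yc^2
  sxy <- sum(xc * yc) - xc * yc
  m <- n - 1
  vx <- sxx / m - (sx / m)^2
  vy <- syy / m - (sy / m)^2
  cv <- sxy / m - (sx / m) * (sy / m)
  if (any(vx <= 0) || any(vy <= 0)) {
    undefined_statistic(sprintf(
      "correlation undefined on leave-one-out subsample %d (constant variable)",
      which(vx <= 0 | vy <= 0)[1]
    ))
  }
  r_loo <- cv / sqrt(vx * vy)
  bad <- which(abs(r_loo) >= 1)
  if (length(bad) > 0) {
    domain_error(sprintf("|r| = 1 on leave-one-out subsample %d", bad[1]))
  }
  jackknife_result(atanh(r_full), atanh(r_loo), n)
}

#' Pool two per-group jackknife results into a contrast
#'
#' Point estimate is group 1 minus group 2 (plug-in or bias-corrected points);
#' the sampling variance is the sum of the per-group jackknife variances,
#' treating the groups as independent.
#'
#' @param j1,j2 `jackknife_result` objects for groups 1 and 2.
#' @param point_method `"analytic"` (difference of plug-in estimates) or
#'   `"jackknife_bias_corrected"`.
#' @return List with `estimate` and `variance`.
#' @export
pooled_jackknife_contrast <- function(j1, j2,
                                      point_method = c("analytic", "jackknife_bias_corrected")) {
  point_method <- match.arg(point_method)
  stopifnot(inherits(j1, "jackknife_result"), inherits(j2, "jackknife_result"))
  est <- if (point_method == "analytic") {
    j1$plug_in - j2$plug_in
  } else {
    j1$bias_corrected - j2$bias_corrected
  }
  list(estimate = est, variance = j1$variance + j2$variance)
}
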