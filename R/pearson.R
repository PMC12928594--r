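# Moment-parameterized Pearson-system sampling. A target is (mean, variance,
# skewness, kurtosis on the non-excess scale); the type is selected by the
# classical kappa criterion on (beta1, beta2) = (skewness^2, kurtosis), a
# standardized variate is drawn from the type-specific standard form, and the
# result is relocated affinely to (mean, variance). Skewness and kurtosis are
# affine invariants, so relocation does not disturb them.

#' Moment target for Pearson-system sampling
#'
#' @param mean Target mean.
#' @param variance Target variance (> 0).
#' @param skewness Target skewness (signed).
#' @param kurtosis Target kurtosis on the non-excess scale (normal = 3). Must
#'   satisfy the feasibility bound `kurtosis > skewness^2 + 1`.
#' @return A `moment_target` list.
#' @examples
#' moment_target(0, 1, 0.5, 3)
#' @export
moment_target <- function(mean = 0, variance = 1, skewness = 0, kurtosis = 3) {
  for (v in list(mean, variance, skewness, kurtosis)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      invalid_input("moment_target: all four moments must be finite scalars")
    }
  }
  if (variance <= 0) invalid_input("moment_target: variance must be positive")
  if (kurtosis <= skewness^2 + 1) {
    domain_error(sprintf(
      "infeasible moment pair: kurtosis (%g) must exceed skewness^2 + 1 = %g",
      kurtosis, skewness^2 + 1
    ))
  }
  structure(list(mean = mean, variance = variance, skewness = skewness,
                 kurtosis = kurtosis), class = "moment_target")
}

#' Classify a (skewness, kurtosis) pair in the Pearson system
#'
#' Applies the classical kappa criterion with \eqn{\beta_1 =} skewness^2 and
#' \eqn{\beta_2 =} kurtosis: \deqn{\kappa = \beta_1(\beta_2+3)^2 /
#' [4(4\beta_2-3\beta_1)(2\beta_2-3\beta_1-6)].} Negative kappa gives the
#' (beta) type I; 0 < kappa < 1 type IV; kappa = 1 type V; kappa > 1 type VI;
#' the boundary \eqn{2\beta_2-3\beta_1-6=0} type III (gamma); and on the
#' symmetric axis \eqn{\beta_1 = 0}: normal at \eqn{\beta_2 = 3}, type II
#' below, type VII above.
#'
#' @param skewness Signed skewness.
#' @param kurtosis Kurtosis on the non-excess scale.
#' @return One of `"normal"`, `"I"`, ..., `"VII"`.
#' @examples
#' classify_pearson_type(1, 3) # "I"
#' @export
classify_pearson_type <- function(skewness, kurtosis) {
  b1 <- skewness^2
  b2 <- kurtosis
  if (b2 <= b1 + 1) {
    domain_error(sprintf(
      "infeasible moment pair: kurtosis (%g) must exceed skewness^2 + 1 = %g",
      b2, b1 + 1
    ))
  }
  eps <- 1e-8
  if (b1 < eps) {
    if (abs(b2 - 3) < eps) return("normal")
    return(if (b2 < 3) "II" else "VII")
  }
  denom3 <- 2 * b2 - 3 * b1 - 6
  if (abs(denom3) < eps) return("III")
  kappa <- b1 * (b2 + 3)^2 / (4 * (4 * b2 - 3 * b1) * denom3)
  if (kappa < 0) return("I")
  if (abs(kappa - 1) < eps) return("V")
  if (kappa < 1) return("IV") else return("VI")
}

# ---- type-specific standardized samplers (mean 0, variance 1) --------------

# Type I: beta(p, q). Closed-form solution hitting both beta1 and beta2.
pearson_i_params <- function(gamma, b2) {
  b1 <- gamma^2
  s <- 6 * (b2 - b1 - 1) / (6 + 3 * b1 - 2 * b2)
  d2 <- b1 * s^2 * (s + 2)^2 / (16 * (s + 1) + b1 * (s + 2)^2)
  d <- sign(gamma) * sqrt(d2) # q - p; q > p gives positive skewness
  p <- (s - d) / 2
  q <- (s + d) / 2
  if (!is.finite(p) || !is.finite(q) || p <= 0 || q <= 0) {
    domain_error(sprintf("type I parameter solution failed for skewness %g, kurtosis %g", gamma, b2))
  }
  c(p = p, q = q)
}

sample_pearson_i <- function(n, gamma, b2) {
  pq <- pearson_i_params(gamma, b2)
  p <- pq[["p"]]; q <- pq[["q"]]
  mu <- p / (p + q)
  sd <- sqrt(p * q / ((p + q)^2 * (p + q + 1)))
  (stats::rbeta(n, p, q) - mu) / sd
}

# Type II: symmetric beta(a, a); excess kurtosis -6/(2a + 3).
sample_pearson_ii <- function(n, b2) {
  a <- 3 / (3 - b2) - 1.5
  if (a <= 0) domain_error(sprintf("type II requires kurtosis in (1, 3); got %g", b2))
  sd <- sqrt(1 / (4 * (2 * a + 1)))
  (stats::rbeta(n, a, a) - 0.5) / sd
}

# Type III: gamma with shape k = 4/skewness^2.
sample_pearson_iii <- function(n, gamma) {
  k <- 4 / gamma^2
  sign(gamma) * (stats::rgamma(n, shape = k) - k) / sqrt(k)
}

# Type V: inverse gamma, shape solved from |skewness| = 4*sqrt(a-2)/(a-3).
sample_pearson_v <- function(n, gamma, b2) {
  skew_fun <- function(a) 4 * sqrt(a - 2) / (a - 3)
  g <- abs(gamma)
  if (g >= skew_fun(4 + 1e-8) || g < 1e-12) {
    domain_error("type V moment pair outside the solvable inverse-gamma range")
  }
  a <- stats::uniroot(function(a) skew_fun(a) - g, c(4 + 1e-8, 1e8), tol = 1e-12)$root
  exk <- (30 * a - 66) / ((a - 3) * (a - 4))
  if (abs(exk - (b2 - 3)) > 1e-4 * max(1, abs(b2 - 3))) {
    domain_error("type V target moments are mutually inconsistent")
  }
  x <- 1 / stats::rgamma(n, shape = a)
  m <- 1 / (a - 1)
  sd <- sqrt(1 / ((a - 1)^2 * (a - 2)))
  sign(gamma) * (x - m) / sd
}

# Type VI: beta-prime(a, b) (ratio of gammas); (a, b) solved numerically from
# the target skewness and excess kurtosis, then verified.
pearson_vi_params <- function(gamma, b2) {
  g <- abs(gamma)
  exk <- b2 - 3
  skew_bp <- function(a, b) 2 * (2 * a + b - 1) / (b - 3) * sqrt((b - 2) / (a * (a + b - 1)))
  exk_bp <- function(a, b) {
    6 * (a * (a + b - 1) * (5 * b - 11) + (b - 1)^2 * (b - 2)) /
      (a * (a + b - 1) * (b - 3) * (b - 4))
  }
  obj <- function(par) {
    a <- exp(par[1]); b <- 4 + exp(par[2])
    (skew_bp(a, b) - g)^2 + (exk_bp(a, b) - exk)^2
  }
  best <- NULL
  for (start in list(c(0, 1), c(1, 2), c(2, 3), c(-1, 0.5), c(3, 1.5))) {
    fit <- tryCatch(
      stats::optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value > 1e-12) {
    convergence_error(sprintf(
      "type VI parameter solve failed for skewness %g, kurtosis %g (residual %g)",
      gamma, b2, if (is.null(best)) NA_real_ else best$value
    ))
  }
  c(a = exp(best$par[1]), b = 4 + exp(best$par[2]))
}

sample_pearson_vi <- function(n, gamma, b2) {
  ab <- pearson_vi_params(gamma, b2)
  a <- ab[["a"]]; b <- ab[["b"]]
  x <- stats::rgamma(n, shape = a) / stats::rgamma(n, shape = b)
  m <- a / (b - 1)
  sd <- sqrt(a * (a + b - 1) / ((b - 2) * (b - 1)^2))
  sign(gamma) * (x - m) / sd
}

# Type VII: scaled Student t with df = 6/(b2 - 3) + 4.
sample_pearson_vii <- function(n, b2) {
  df <- 6 / (b2 - 3) + 4
  stats::rt(n, df) * sqrt((df - 2) / df)
}

# Type IV: no standard-form sampler exists; draw by numeric quantile inversion
# of the standardized Pearson density, whose log has a closed form from the
# defining differential equation f'/f = -(a + x)/(b0 + b1 x + b2 x^2).
pearson_iv_logdensity <- function(gamma, b2) {
  b1sq <- gamma^2
  A <- 10 * b2 - 12 * b1sq - 18
  if (abs(A) < 1e-10) {
    convergence_error("type IV density degenerates at these moments (criterion denominator ~ 0)")
  }
  a <- gamma * (b2 + 3) / A
  c0 <- (4 * b2 - 3 * b1sq) / A
  c2 <- (2 * b2 - 3 * b1sq - 6) / A
  c1 <- a
  disc <- 4 * c2 * c0 - c1^2
  if (c2 <= 0 || disc <= 0) {
    convergence_error("type IV density solve failed: quadratic has real roots")
  }
  if (1 / c2 <= 5) {
    domain_error("type IV tails too heavy: fourth moment does not exist for this target")
  }
  sq <- sqrt(disc)
  Q <- function(x) c0 + c1 * x + c2 * x^2
  function(x) {
    -((1 / (2 * c2)) * (log(Q(x)) - log(Q(0))) +
        (a - c1 / (2 * c2)) * (2 / sq) *
          (atan((2 * c2 * x + c1) / sq) - atan(c1 / sq)))
  }
}

sample_pearson_iv <- function(n, gamma, b2, grid_points = 2^15 + 1) {
  logf <- pearson_iv_logdensity(gamma, b2)
  L <- 16
  repeat {
    if (exp(logf(L)) < 1e-13 && exp(logf(-L)) < 1e-13) break
    L <- L * 2
    if (L > 1e6) convergence_error("type IV support expansion failed to find negligible tails")
  }
  xs <- seq(-L, L, length.out = grid_points)
  lf <- logf(xs)
  f <- exp(lf - max(lf))
  dx <- xs[2] - xs[1]
  cdf <- cumsum((f[-1] + f[-length(f)]) / 2) * dx
  cdf <- c(0, cdf) / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0) # strictly increasing knots for inversion
  stats::approx(cdf[keep], xs[keep], xout = stats::runif(n), rule = 2)$y
}

#' Draw random samples from the Pearson distribution system
#'
#' Samples `n` independent values whose population mean, variance, skewness,
#' and kurtosis equal the target. The Pearson type is selected by
#' [classify_pearson_type()]; types I/II use beta draws, III gamma, V inverse
#' gamma, VI beta-prime (gamma ratio), VII scaled Student t, and IV numeric
#' quantile inversion of the Pearson density. The standardized draw is then
#' relocated to the target mean and variance.
#'
#' @param n Number of draws.
#' @param target A [moment_target()].
#' @return Numeric vector of length `n`.
#' @examples
#' set.seed(42)
#' x <- sample_pearson(1e4, moment_target(5, 2, 1, 3))
#' c(mean(x), var(x))
#' @export
sample_pearson <- function(n, target) {
  if (!inherits(target, "moment_target")) {
    target <- do.call(moment_target, as.list(target))
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    invalid_input("sample_pearson: n must be a positive integer")
  }
  type <- classify_pearson_type(target$skewness, target$kurtosis)
  z <- switch(type,
    normal = stats::rnorm(n),
    I = sample_pearson_i(n, target$skewness, target$kurtosis),
    II = sample_pearson_ii(n, target$kurtosis),
    III = sample_pearson_iii(n, target$skewness),
    IV = sample_pearson_iv(n, target$skewness, target$kurtosis),
    V = sample_pearson_v(n, target$skewness, target$kurtosis),
    VI = sample_pearson_vi(n, target$skewness, target$kurtosis),
    VII = sample_pearson_vii(n, target$kurtosis)
  )
  target$mean + sqrt(target$variance) * z
}

#' Draw a bivariate normal sample with target correlation
#'
#' Standard-normal marginals with population correlation `r`, built from the
#' Cholesky factor of the 2x2 correlation matrix: `y = r x + sqrt(1 - r^2) z`.
#'
#' @param n Number of pairs.
#' @param r Target correlation in \eqn{[-1, 1]}.
#' @return A list with numeric vectors `x` and `y` of length `n`.
#' @examples
#' set.seed(1)
#' d <- sample_bivariate_normal(1e4, 0.8)
#' cor(d$x, d$y)
#' @export
sample_bivariate_normal <- function(n, r) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || abs(r) > 1) {
    invalid_input("sample_bivariate_normal: r must be a scalar in [-1, 1]")
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    invalid_input("sample_bivariate_normal: n must be a positive integer")
  }
  x <- stats::rnorm(n)
  y <- r * x + sqrt(1 - r^2) * stats::rnorm(n)
  list(x = x, y = y)
}
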