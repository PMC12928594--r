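# Independent direct-summation oracles, deliberately naive so they share no
# code with the implementation.

oracle_skewness <- function(x) {
  n <- length(x)
  xb <- sum(x) / n
  m2 <- sum((x - xb)^2) / n
  m3 <- sum((x - xb)^3) / n
  (m3 / m2^(3 / 2)) * sqrt(n * (n - 1)) / (n - 2)
}

oracle_excess_kurtosis <- function(x) {
  n <- length(x)
  xb <- sum(x) / n
  s2 <- sum((x - xb)^2)
  s4 <- sum((x - xb)^4)
  n * (n + 1) * (n - 1) / ((n - 2) * (n - 3)) * s4 / s2^2 -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

oracle_jackknife_variance <- function(statistic, x) {
  n <- length(x)
  loo <- sapply(seq_len(n), function(i) statistic(x[-i]))
  (n - 1) / n * sum((loo - mean(loo))^2)
}

# Empirical Monte-Carlo SE of a statistic over a large sample, from
# non-overlapping blocks; used for 4-MCSE moment-recovery tolerances.
block_mcse <- function(x, stat, blocks = 25) {
  idx <- cut(seq_along(x), blocks, labels = FALSE)
  vals <- vapply(seq_len(blocks), function(b) stat(x[idx == b]), numeric(1))
  stats::sd(vals) / sqrt(blocks)
}

# Synthetic meta-analytic inputs drawn from the random-effects model itself.
make_zr_effects <- function(k, mu, tau2, n = 100, seed = 1) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    theta <- mu + rnorm(1, 0, sqrt(tau2))
    y <- theta + rnorm(1, 0, sqrt(2 / (n - 3)))
    momentdiff:::new_effect_size("delta_zr", y, 2 / (n - 3), n, n,
                                 "analytic", "analytic")
  })
}

# Standard two-group fixtures used across test files.
make_paired_groups <- function(seed = 42, n1 = 80, n2 = 60, r1 = 0.5, r2 = 0.2) {
  set.seed(seed)
  d1 <- sample_bivariate_normal(n1, r1)
  d2 <- sample_bivariate_normal(n2, r2)
  list(
    g1 = group_sample(d1$x, d1$y, label = "male"),
    g2 = group_sample(d2$x, d2$y, label = "female")
  )
}

make_moment_groups <- function(seed = 42, n1 = 80, n2 = 60, sk1 = 0.8, sk2 = 0) {
  set.seed(seed)
  list(
    g1 = group_sample(sample_pearson(n1, moment_target(0, 1, sk1, 3.2)), label = "male"),
    g2 = group_sample(sample_pearson(n2, moment_target(0, 1, sk2, 3.2)), label = "female")
  )
}
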