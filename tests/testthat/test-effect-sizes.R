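test_that("contrasts are zero for identical groups and antisymmetric under swap", {
  pg <- make_paired_groups()
  mg <- make_moment_groups()
  cases <- list(
    list(fun = function(a, b) delta_skewness(a, b, warn_small_n = FALSE), g = mg),
    list(fun = function(a, b) delta_kurtosis(a, b, warn_small_n = FALSE), g = mg),
    list(fun = delta_zr, g = pg),
    list(fun = function(a, b) lnRR(group_sample(exp(a$values), label = a$label),
                                   group_sample(exp(b$values), label = b$label)), g = mg),
    list(fun = function(a, b) lnVR(a, b), g = mg)
  )
  for (cs in cases) {
    same <- cs$fun(cs$g$g1, cs$g$g1)
    expect_equal(same$estimate, 0)
    fwd <- cs$fun(cs$g$g1, cs$g$g2)
    rev <- cs$fun(cs$g$g2, cs$g$g1)
    expect_equal(rev$estimate, -fwd$estimate, tolerance = 1e-12)
    expect_equal(rev$sampling_variance, fwd$sampling_variance, tolerance = 1e-12)
  }
})

test_that("analytic contrast variances equal the sum of group variances at rho = 0", {
  mg <- make_moment_groups(n1 = 10, n2 = 10)
  e <- delta_skewness(mg$g1, mg$g2, variance_method = "analytic", warn_small_n = FALSE)
  expect_equal(e$sampling_variance, 2 * skewness_sampling_variance(10), tolerance = 1e-12)
  expect_equal(e$sampling_variance, 0.94405594, tolerance = 1e-6)
  ek <- delta_kurtosis(mg$g1, mg$g2, variance_method = "analytic", warn_small_n = FALSE)
  expect_equal(ek$sampling_variance, 2 * kurtosis_sampling_variance(10), tolerance = 1e-12)
})

test_that("delta_zr reproduces the atanh arithmetic and dependence algebra", {
  e <- effect_from_summaries("delta_zr", 0.5, 0.3, 103, 53)
  expect_equal(e$estimate, atanh(0.5) - atanh(0.3), tolerance = 1e-12)
  expect_equal(e$estimate, 0.2397865, tolerance = 1e-6)
  expect_equal(e$sampling_variance, 0.01 + 0.02)
  # perfect sampling dependence with equal n cancels the variance entirely
  e0 <- effect_from_summaries("delta_zr", 0.5, 0.3, 50, 50, dep = dependence_spec(rho_zr = 1))
  expect_equal(e0$sampling_variance, 0, tolerance = 1e-12)
  pg <- make_paired_groups(n1 = 50, n2 = 50)
  ej <- delta_zr(pg$g1, pg$g2, variance_method = "jackknife")
  expect_gt(ej$sampling_variance, 0)
  expect_equal(ej$estimate, delta_zr(pg$g1, pg$g2)$estimate)
})

test_that("summary-based effects agree exactly with the raw-data analytic path", {
  mg <- make_moment_groups()
  raw <- delta_skewness(mg$g1, mg$g2, variance_method = "analytic", warn_small_n = FALSE)
  summ <- effect_from_summaries("delta_sk", sample_skewness(mg$g1$values),
                                sample_skewness(mg$g2$values), mg$g1$n, mg$g2$n)
  expect_equal(summ$estimate, raw$estimate, tolerance = 1e-12)
  expect_equal(summ$sampling_variance, raw$sampling_variance, tolerance = 1e-12)
  rawk <- delta_kurtosis(mg$g1, mg$g2, variance_method = "analytic", warn_small_n = FALSE)
  summk <- effect_from_summaries("delta_ku", sample_excess_kurtosis(mg$g1$values),
                                 sample_excess_kurtosis(mg$g2$values), mg$g1$n, mg$g2$n)
  expect_equal(summk$estimate, rawk$estimate, tolerance = 1e-12)
  pg <- make_paired_groups()
  rawz <- delta_zr(pg$g1, pg$g2)
  summz <- effect_from_summaries("delta_zr",
                                 pearson_correlation(pg$g1$values, pg$g1$second_values),
                                 pearson_correlation(pg$g2$values, pg$g2$second_values),
                                 pg$g1$n, pg$g2$n)
  expect_equal(summz$estimate, rawz$estimate, tolerance = 1e-12)
  expect_equal(summz$sampling_variance, rawz$sampling_variance, tolerance = 1e-12)
  expect_equal(effect_from_summaries("delta_sk", 1, -1, 100, 100)$estimate, 2)
})

test_that("Wald intervals use the normal quantile and scale with the variance", {
  e <- momentdiff:::new_effect_size("delta_sk", 0, 1, 50, 50, "analytic", "analytic")
  ci <- confidence_interval(e, 0.95)
  expect_equal(unname(ci), c(-1.959964, 1.959964), tolerance = 1e-6)
  e4 <- momentdiff:::new_effect_size("delta_sk", 0, 4, 50, 50, "analytic", "analytic")
  expect_equal(unname(diff(confidence_interval(e4, 0.95)) / diff(ci)), 2, tolerance = 1e-12)
  e0 <- momentdiff:::new_effect_size("delta_sk", 0.3, 0, 50, 50, "analytic", "analytic")
  expect_equal(unname(confidence_interval(e0, 0.95)), c(0.3, 0.3))
  expect_error(confidence_interval(e, 1.2), class = "momentdiff_invalid_input")
})

test_that("lnRR and lnVR match their published formulas and a simulation check", {
  set.seed(20)
  g1 <- group_sample(rnorm(2000, 10, 2), label = "a")
  g2 <- group_sample(rnorm(2000, 10, 4), label = "b")
  ev <- lnVR(g1, g2)
  expect_equal(ev$estimate, -log(2), tolerance = 0.05)
  expect_error(lnRR(group_sample(c(-3, 1, 1), label = "neg"), g2),
               class = "momentdiff_domain_error")
  # delta-method variance formulas track the Monte-Carlo variance
  reps <- replicate(1500, {
    a <- group_sample(rnorm(100, 10, 2), label = "a")
    b <- group_sample(rnorm(100, 12, 3), label = "b")
    c(lnRR(a, b)$estimate, lnRR(a, b)$sampling_variance,
      lnVR(a, b)$estimate, lnVR(a, b)$sampling_variance)
  })
  expect_equal(mean(reps[2, ]) / var(reps[1, ]), 1, tolerance = 0.15)
  expect_equal(mean(reps[4, ]) / var(reps[3, ]), 1, tolerance = 0.15)
})

test_that("nominal 95% delta-Zr intervals cover at small-to-moderate n", {
  hits <- vapply(1:2500, function(i) {
    set.seed(3000 + i)
    d1 <- sample_bivariate_normal(20, 0.4)
    d2 <- sample_bivariate_normal(20, 0.1)
    e <- delta_zr(group_sample(d1$x, d1$y, "a"), group_sample(d2$x, d2$y, "b"))
    ci <- confidence_interval(e, 0.95)
    truth <- atanh(0.4) - atanh(0.1)
    ci[1] <= truth && truth <= ci[2]
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.015)
})

test_that("small groups trigger the recommended-n warning for moment contrasts only", {
  mg <- make_moment_groups(n1 = 20, n2 = 20)
  expect_warning(delta_skewness(mg$g1, mg$g2), class = "momentdiff_small_n")
  expect_warning(delta_kurtosis(mg$g1, mg$g2), class = "momentdiff_small_n")
  expect_no_warning(delta_skewness(mg$g1, mg$g2, warn_small_n = FALSE))
  big <- make_moment_groups(n1 = 60, n2 = 60)
  expect_no_warning(delta_skewness(big$g1, big$g2))
})

test_that("effect tables keep a stable schema and propagate stratum tags", {
  mg <- make_moment_groups()
  e1 <- delta_skewness(mg$g1, mg$g2, warn_small_n = FALSE)
  e1$stratum <- list(center = "A", strain = "s1")
  e2 <- delta_kurtosis(mg$g1, mg$g2, warn_small_n = FALSE)
  tab <- effects_to_table(list(e1, e2))
  expect_equal(names(tab)[1:7],
               c("effect_kind", "estimate", "sampling_variance", "n1", "n2",
                 "point_method", "variance_method"))
  expect_equal(tab$center, c("A", NA))
  expect_equal(nrow(tab), 2)
})

test_that("group errors are annotated with the offending group label", {
  bad <- group_sample(rep(1, 10), label = "flat")
  ok <- make_moment_groups()$g1
  expect_error(delta_skewness(ok, bad, warn_small_n = FALSE), "flat",
               class = "momentdiff_undefined_statistic")
})
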