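test_that("default scenario grids enumerate the expected cell counts", {
  zr <- build_scenarios("zr")
  expect_equal(nrow(zr), 768)
  expect_equal(unname(table(zr$n)["10"]), 64L)
  sk <- build_scenarios("skew")
  expect_equal(nrow(sk), 1200)
  expect_equal(unname(table(sk$n)["10"]), 100L)
  ku <- build_scenarios("kurt")
  expect_equal(nrow(ku), 1200)
  expect_equal(nrow(build_scenarios(c("skew", "kurt", "zr"))), 3168)
  # singleton grids collapse to one scenario
  expect_equal(nrow(build_scenarios("zr", n_set = 50, r_values = 0.3)), 1)
  # deterministic, sorted enumeration
  expect_identical(build_scenarios("zr"), build_scenarios("zr"))
  expect_false(is.unsorted(zr$scenario_id))
  expect_error(build_scenarios("zr", r_values = c(0, 2)), class = "momentdiff_config_error")
  expect_error(build_scenarios("skew", mean_conditions = "weird"),
               class = "momentdiff_config_error")
})

test_that("scenario truths encode the configured contrasts", {
  sk <- build_scenarios("skew", n_set = 10)
  expect_equal(sk$truth, sk$sk1 - sk$sk2)
  ku <- build_scenarios("kurt", n_set = 10)
  expect_equal(ku$truth, ku$ku1 - ku$ku2)
  zr <- build_scenarios("zr", n_set = 10)
  expect_equal(zr$truth, atanh(zr$r1) - atanh(zr$r2))
})

test_that("replicate tables are reproducible and respect the seed stream", {
  s <- build_scenarios("zr", n_set = 30, r_values = c(0.2, 0.4))[1, ]
  a <- run_scenario(s, reps = 50, root_seed = 11)
  b <- run_scenario(s, reps = 50, root_seed = 11)
  expect_identical(a, b)
  c_ <- run_scenario(s, reps = 50, root_seed = 12)
  expect_false(identical(a$est_analytic, c_$est_analytic))
})

test_that("null scenarios are unbiased within Monte-Carlo error", {
  for (fam in c("skew", "kurt", "zr")) {
    s <- switch(fam,
      skew = build_scenarios("skew", n_set = 50, sk_values = 0.5,
                             variance_conditions = "equal", mean_conditions = "equal"),
      kurt = build_scenarios("kurt", n_set = 50, ku_values = 4,
                             variance_conditions = "equal", mean_conditions = "equal"),
      zr = build_scenarios("zr", n_set = 50, r_values = 0.4)
    )
    r <- run_scenario(s, reps = 600, root_seed = 21)
    p <- summarize_performance(r, truth = 0)
    for (i in seq_len(nrow(p))) {
      expect_lt(abs(p$bias[i]), 4 * p$bias_mcse[i])
    }
  }
})

test_that("performance metrics satisfy their definitional identities", {
  fake <- data.frame(
    scenario_id = "toy", replicate = 1:400,
    est_analytic = rep(1.5, 400), est_jackknife_bc = rep(1.5, 400),
    var_analytic = rep(0.1, 400), var_jackknife = rep(0.1, 400),
    reason = NA_character_
  )
  p <- summarize_performance(fake, truth = 1.5)
  expect_equal(p$bias, rep(0, 4))
  expect_equal(p$coverage, rep(1, 4))
  expect_true(all(is.na(p$rel_var_bias))) # zero MC variance is undefined, not 0
  # variance estimator fixed at the true MC variance: relative bias ~ 0
  set.seed(31)
  est <- rnorm(4000, 0, 0.3)
  fake2 <- data.frame(
    scenario_id = "toy2", replicate = seq_along(est),
    est_analytic = est, est_jackknife_bc = est,
    var_analytic = var(est), var_jackknife = var(est), reason = NA_character_
  )
  p2 <- summarize_performance(fake2, truth = 0)
  expect_equal(p2$rel_var_bias, rep(0, 4), tolerance = 1e-10)
  expect_equal(p2$coverage_mcse, sqrt(p2$coverage * (1 - p2$coverage) / 4000))
  # failed replicates are excluded and counted
  fake2$est_analytic[1:10] <- NA
  fake2$reason[1:10] <- "undefined"
  p3 <- summarize_performance(fake2, truth = 0)
  expect_equal(p3$n_reps_effective[p3$estimator_pairing == "analytic_analytic"], 3990)
})

test_that("the Monte-Carlo variance of delta-Zr converges to the analytic value", {
  s <- build_scenarios("zr", n_set = 500, r_values = c(0.2, 0.4))
  s <- s[s$r1 == 0.4 & s$r2 == 0.2, ]
  r <- run_scenario(s, reps = 2500, root_seed = 41)
  ratio <- fisher_z_variance(500) * 2 / var(r$est_analytic)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("run_study emits all pairings, caches per scenario, and rejects bad caches", {
  scen <- build_scenarios("zr", n_set = c(10, 20), r_values = c(0, 0.4))
  cache <- withr::local_tempdir()
  perf <- run_study(scen, reps = 40, root_seed = 51, cache_dir = cache)
  expect_equal(nrow(perf), nrow(scen) * 4)
  expect_setequal(unique(perf$estimator_pairing),
                  c("analytic_analytic", "analytic_jackknife",
                    "jackknife_bc_jackknife", "jackknife_bc_analytic"))
  # second run reuses the cache (CSV round-trip, so equal to text precision)
  perf2 <- run_study(scen, reps = 40, root_seed = 51, cache_dir = cache)
  expect_equal(perf, perf2, tolerance = 1e-12)
  # recomputation without a cache is bit-identical
  expect_identical(run_study(scen, reps = 40, root_seed = 51),
                   run_study(scen, reps = 40, root_seed = 51))
  # a cache file with a foreign schema must be a hard error
  f <- list.files(cache, full.names = TRUE)[1]
  write.csv(data.frame(bogus = 1), f, row.names = FALSE)
  expect_error(run_study(scen, reps = 40, root_seed = 51, cache_dir = cache),
               class = "momentdiff_config_error")
})

test_that("meta-performance: k = 1 collapses to the single study and homogeneous pooling covers", {
  one <- run_meta_performance("delta_zr", true_effect = 0.2, tau2 = 0, k = 1,
                              n_per_group = 60, meta_reps = 3, root_seed = 61)
  reps <- attr(one, "replicates")
  # with k = 1 the pooled estimate is the single study's effect: tau2 = 0 and
  # the pooled SE is that effect's sampling SE, sqrt(2/(n-3))
  expect_equal(reps$se, rep(sqrt(2 / 57), 3), tolerance = 1e-12)
  expect_equal(one$mean_tau2_hat, 0)
  again <- run_meta_performance("delta_zr", true_effect = 0.2, tau2 = 0, k = 1,
                                n_per_group = 60, meta_reps = 3, root_seed = 61)
  expect_identical(reps, attr(again, "replicates"))

  hom <- run_meta_performance("delta_zr", true_effect = 0.2, tau2 = 0, k = 10,
                              n_per_group = 100, meta_reps = 150, root_seed = 62)
  expect_lt(abs(hom$coverage - 0.95), 4 * sqrt(0.95 * 0.05 / 150) + 0.01)
  expect_lt(abs(hom$bias), 4 * hom$bias_mcse)
})
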