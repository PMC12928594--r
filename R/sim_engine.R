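# Monte-Carlo engine: seeded replicates per scenario, all four estimator
# pairings (analytic/jackknife points x analytic/jackknife variances), and
# Morris-style performance metrics with Monte-Carlo standard errors.

estimator_pairings <- function() {
  list(
    analytic_analytic = c(point = "est_analytic", variance = "var_analytic"),
    analytic_jackknife = c(point = "est_analytic", variance = "var_jackknife"),
    jackknife_bc_jackknife = c(point = "est_jackknife_bc", variance = "var_jackknife"),
    jackknife_bc_analytic = c(point = "est_jackknife_bc", variance = "var_analytic")
  )
}

replicate_once <- function(scenario) {
  n <- scenario$n
  if (scenario$family == "zr") {
    d1 <- sample_bivariate_normal(n, scenario$r1)
    d2 <- sample_bivariate_normal(n, scenario$r2)
    j1 <- jackknife_correlation(d1$x, d1$y)
    j2 <- jackknife_correlation(d2$x, d2$y)
    list(
      est_analytic = atanh(pearson_correlation(d1$x, d1$y)) -
        atanh(pearson_correlation(d2$x, d2$y)),
      est_jackknife_bc = j1$bias_corrected - j2$bias_corrected,
      var_analytic = fisher_z_variance(n) * 2,
      var_jackknife = j1$variance + j2$variance
    )
  } else {
    kind <- if (scenario$family == "skew") "skewness" else "kurtosis"
    x1 <- sample_pearson(n, moment_target(scenario$mean1, scenario$var1,
                                          scenario$sk1, scenario$ku1))
    x2 <- sample_pearson(n, moment_target(scenario$mean2, scenario$var2,
                                          scenario$sk2, scenario$ku2))
    j1 <- jackknife_moments(x1, kind)
    j2 <- jackknife_moments(x2, kind)
    var_fun <- if (kind == "skewness") skewness_sampling_variance else kurtosis_sampling_variance
    list(
      est_analytic = j1$plug_in - j2$plug_in,
      est_jackknife_bc = j1$bias_corrected - j2$bias_corrected,
      var_analytic = var_fun(n) * 2,
      var_jackknife = j1$variance + j2$variance
    )
  }
}

#' Run all replicates of one scenario
#'
#' Draws `reps` fresh two-group datasets for the scenario and records, per
#' replicate, the analytic and jackknife-bias-corrected point estimates and
#' the analytic and jackknife sampling variances. Each replicate's RNG seed is
#' a pure function of `(root_seed, scenario_id, replicate)`, so results are
#' reproducible and individual replicates can be re-run in isolation.
#' Replicates on which a statistic is undefined are kept as NA rows with a
#' reason code rather than silently redrawn (redrawing would bias
#' null-boundary scenarios); the scenario aborts if more than half fail.
#'
#' @param scenario One row of [build_scenarios()] (data.frame or list).
#' @param reps Number of Monte-Carlo replicates (paper-scale default 2500).
#' @param root_seed Integer root seed.
#' @return A data.frame with one row per replicate: `scenario_id`,
#'   `replicate`, `est_analytic`, `est_jackknife_bc`, `var_analytic`,
#'   `var_jackknife`, `reason` (NA when the replicate succeeded).
#' @export
run_scenario <- function(scenario, reps = 2500, root_seed = 1) {
  if (is.data.frame(scenario)) {
    if (nrow(scenario) != 1) invalid_input("run_scenario expects a single scenario row")
    scenario <- as.list(scenario)
  }
  if (!is.numeric(reps) || reps < 1) invalid_input("reps must be >= 1")
  reps <- as.integer(reps)
  cols <- c("est_analytic", "est_jackknife_bc", "var_analytic", "var_jackknife")
  out <- matrix(NA_real_, nrow = reps, ncol = 4, dimnames = list(NULL, cols))
  reason <- rep(NA_character_, reps)
  for (i in seq_len(reps)) {
    set.seed(derive_seed(root_seed, paste0(scenario$scenario_id, "#", i)))
    res <- tryCatch(replicate_once(scenario), momentdiff_error = function(e) e)
    if (inherits(res, "condition")) {
      reason[i] <- conditionMessage(res)
    } else {
      out[i, ] <- unlist(res)[cols]
    }
  }
  n_fail <- sum(!is.na(reason))
  if (n_fail > reps / 2) {
    md_stop("momentdiff_invalid_input", sprintf(
      "scenario %s: %d of %d replicates failed (first reason: %s)",
      scenario$scenario_id, n_fail, reps, reason[!is.na(reason)][1]
    ))
  }
  data.frame(scenario_id = scenario$scenario_id, replicate = seq_len(reps),
             out, reason = reason, stringsAsFactors = FALSE)
}

# Delta-method MCSE for the relative variance bias A/B - 1 with A = mean(v),
# B = Var_MC(theta_hat).
rel_var_bias_mcse <- function(v, est) {
  R <- length(est)
  A <- mean(v)
  cest <- est - mean(est)
  B <- stats::var(est)
  var_A <- stats::var(v) / R
  var_B <- (mean(cest^4) - ((R - 3) / (R - 1)) * B^2) / R
  cov_AB <- stats::cov(v, cest^2) / R
  sqrt(max(0, var_A / B^2 + A^2 * var_B / B^4 - 2 * A * cov_AB / B^3))
}

#' Summarize Monte-Carlo performance for every estimator pairing
#'
#' Computes, per pairing of point estimator and variance estimator:
#' bias \eqn{= \mathrm{mean}(\hat\theta) - \theta}; relative variance bias
#' \eqn{= [\mathrm{mean}(\hat v) - \mathrm{Var}_{MC}(\hat\theta)] /
#' \mathrm{Var}_{MC}(\hat\theta)}; empirical coverage of symmetric Wald
#' intervals at `level`; and Monte-Carlo standard errors (bias:
#' \eqn{\sqrt{\mathrm{Var}_{MC}/R}}; coverage: \eqn{\sqrt{c(1-c)/R}};
#' relative variance bias: delta method). Failed replicates are excluded and
#' counted in `n_reps_effective`.
#'
#' @param results Replicate table from [run_scenario()].
#' @param truth True effect value for the scenario.
#' @param level Nominal confidence level (default 0.95).
#' @return A data.frame with one row per estimator pairing.
#' @export
summarize_performance <- function(results, truth, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1) invalid_input("level must be in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  rows <- lapply(names(estimator_pairings()), function(pname) {
    p <- estimator_pairings()[[pname]]
    est <- results[[p[["point"]]]]
    v <- results[[p[["variance"]]]]
    ok <- is.finite(est) & is.finite(v)
    est <- est[ok]; v <- v[ok]
    R <- length(est)
    if (R < 2) invalid_input("summarize_performance needs at least 2 effective replicates")
    var_mc <- stats::var(est)
    if (var_mc <= 0) {
      rvb <- NA_real_; rvb_mcse <- NA_real_
    } else {
      rvb <- mean(v) / var_mc - 1
      rvb_mcse <- rel_var_bias_mcse(v, est)
    }
    cov_hit <- abs(est - truth) <= z * sqrt(v)
    cv <- mean(cov_hit)
    data.frame(
      scenario_id = results$scenario_id[1],
      estimator_pairing = pname,
      n_reps_effective = R,
      bias = mean(est) - truth,
      bias_mcse = sqrt(var_mc / R),
      rel_var_bias = rvb,
      rel_var_bias_mcse = rvb_mcse,
      coverage = cv,
      coverage_mcse = sqrt(cv * (1 - cv) / R),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run a full simulation study
#'
#' Runs every scenario in the table and returns the tidy performance table
#' (one row per scenario x estimator pairing), carrying the scenario
#' descriptors alongside the metrics. With `cache_dir`, per-scenario results
#' are cached as CSV keyed on (scenario id, reps, seed); a cached file whose
#' schema does not match the current output is a hard error, never silently
#' reused.
#'
#' @param scenarios Scenario table from [build_scenarios()].
#' @param reps Replicates per scenario.
#' @param root_seed Integer root seed.
#' @param level Nominal confidence level for the coverage metric.
#' @param cache_dir Optional directory for per-scenario CSV caching.
#' @param csv Optional path: write the performance table as CSV.
#' @param progress Print a line every `progress` scenarios (0 = silent).
#' @return The performance data.frame.
#' @export
run_study <- function(scenarios, reps = 2500, root_seed = 1, level = 0.95,
                      cache_dir = NULL, csv = NULL, progress = 0) {
  if (!is.data.frame(scenarios) || nrow(scenarios) < 1) {
    config_error("scenarios must be a non-empty data.frame from build_scenarios()")
  }
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  out <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    s <- scenarios[i, , drop = FALSE]
    cache_file <- if (!is.null(cache_dir)) {
      key <- gsub("[^A-Za-z0-9_.=-]", "-", sprintf("%s_reps%d_seed%d", s$scenario_id, reps, root_seed))
      file.path(cache_dir, paste0(key, ".csv"))
    }
    perf <- NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      perf <- utils::read.csv(cache_file, stringsAsFactors = FALSE)
    }
    if (is.null(perf)) {
      repl <- run_scenario(s, reps = reps, root_seed = root_seed)
      perf <- summarize_performance(repl, truth = s$truth, level = level)
      if (!is.null(cache_file)) utils::write.csv(perf, cache_file, row.names = FALSE)
    }
    merged <- cbind(s[rep(1, nrow(perf)), setdiff(names(s), "scenario_id"), drop = FALSE],
                    perf)
    if (i > 1 && !identical(names(merged), names(out[[1]]))) {
      md_stop("momentdiff_config_error", sprintf(
        "cached results for scenario %s have a mismatched schema; clear the cache", s$scenario_id
      ))
    }
    out[[i]] <- merged
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("scenario %d / %d done", i, nrow(scenarios)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(csv)) utils::write.csv(res, csv, row.names = FALSE)
  res
}

#' Evaluate the effect sizes inside a meta-analytic pipeline
#'
#' Simulates `meta_reps` meta-analyses: each draws `k` study-level true
#' effects from \eqn{N(\theta, \tau^2)}, generates a two-group dataset per
#' study (Pearson draws for the moment contrasts, bivariate normal for the
#' correlation contrast), computes the per-study effect size with the
#' recommended estimator pairing, and pools with [random_effects_meta()].
#' Reports bias and coverage of the pooled estimate and mean recovered
#' \eqn{\hat\tau^2}.
#'
#' @param effect_kind One of `"delta_sk"`, `"delta_ku"`, `"delta_zr"`.
#' @param true_effect Overall true effect \eqn{\theta}. Group 2's parameter is
#'   held at its reference (skewness 0, kurtosis 3, or r = 0.2) and group 1's
#'   follows the study-level effect.
#' @param tau2 Between-study variance.
#' @param k Studies per meta-analysis.
#' @param n_per_group Per-group sample size in each study.
#' @param meta_reps Number of simulated meta-analyses.
#' @param root_seed Integer root seed.
#' @param weighting Passed to [random_effects_meta()]; `"auto"` picks
#'   sample-size weights for `delta_ku`, inverse-variance otherwise.
#' @param level Confidence level for pooled-estimate coverage.
#' @return A one-row data.frame of performance metrics, with the per-replicate
#'   table attached as attribute `"replicates"`.
#' @export
run_meta_performance <- function(effect_kind = c("delta_zr", "delta_sk", "delta_ku"),
                                 true_effect = 0.2, tau2 = 0.05, k = 20,
                                 n_per_group = 100, meta_reps = 200,
                                 root_seed = 1, weighting = "auto", level = 0.95) {
  effect_kind <- match.arg(effect_kind)
  base_z <- atanh(0.2)
  rows <- vector("list", meta_reps)
  for (m in seq_len(meta_reps)) {
    set.seed(derive_seed(root_seed, paste0("meta_", effect_kind, "#", m)))
    theta_i <- true_effect + stats::rnorm(k, 0, sqrt(tau2))
    effs <- vector("list", k)
    for (j in seq_len(k)) {
      effs[[j]] <- switch(effect_kind,
        delta_zr = {
          r1 <- tanh(base_z + theta_i[j])
          d1 <- sample_bivariate_normal(n_per_group, r1)
          d2 <- sample_bivariate_normal(n_per_group, 0.2)
          delta_zr(group_sample(d1$x, d1$y, "g1"), group_sample(d2$x, d2$y, "g2"))
        },
        delta_sk = {
          sk1 <- theta_i[j]
          if (sk1^2 + 1 >= 3) domain_error("study-level skewness infeasible at kurtosis 3")
          x1 <- sample_pearson(n_per_group, moment_target(0, 1, sk1, 3))
          x2 <- sample_pearson(n_per_group, moment_target(0, 1, 0, 3))
          delta_skewness(group_sample(x1, label = "g1"), group_sample(x2, label = "g2"),
                         warn_small_n = FALSE)
        },
        delta_ku = {
          ku1 <- 3 + theta_i[j]
          if (ku1 <= 1) domain_error("study-level kurtosis infeasible")
          x1 <- sample_pearson(n_per_group, moment_target(0, 1, 0, ku1))
          x2 <- sample_pearson(n_per_group, moment_target(0, 1, 0, 3))
          delta_kurtosis(group_sample(x1, label = "g1"), group_sample(x2, label = "g2"),
                         warn_small_n = FALSE)
        }
      )
    }
    fit <- random_effects_meta(effs, weighting = weighting, level = level)
    rows[[m]] <- data.frame(
      replicate = m,
      pooled = fit$pooled_estimate,
      se = fit$pooled_se,
      tau2_hat = sum(fit$tau2_components),
      hit = fit$ci[1] <= true_effect && true_effect <= fit$ci[2]
    )
  }
  tab <- do.call(rbind, rows)
  cv <- mean(tab$hit)
  out <- data.frame(
    effect_kind = effect_kind,
    k = k,
    n_per_group = n_per_group,
    meta_reps = meta_reps,
    true_effect = true_effect,
    tau2 = tau2,
    bias = mean(tab$pooled) - true_effect,
    bias_mcse = stats::sd(tab$pooled) / sqrt(meta_reps),
    coverage = cv,
    coverage_mcse = sqrt(cv * (1 - cv) / meta_reps),
    mean_tau2_hat = mean(tab$tau2_hat),
    tau2_hat_mcse = stats::sd(tab$tau2_hat) / sqrt(meta_reps),
    stringsAsFactors = FALSE
  )
  attr(out, "replicates") <- tab
  out
}
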