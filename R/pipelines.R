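# High-level pipelines behind the command-line entry point
# (inst/cli/momentdiff) and convenient for scripted use.

#' Study table -> effect-size CSV
#'
#' Reads a long-format study table, computes per-stratum effects, and writes
#' the effect-size CSV. Strata with undefined statistics yield NA rows with a
#' reason code; the pipeline only fails if every row failed.
#'
#' @param input Path to the study-table CSV (or a data.frame).
#' @param output Path for the effect-size CSV (NULL to skip writing).
#' @param types Effect types (see [effect_table()]).
#' @param group_col,trait_cols,stratum_cols Column mapping (see
#'   [read_study_table()]).
#' @param group_order Optional: which group label is group 1 (first element).
#' @param dep A [dependence_spec()].
#' @return The effect-size data.frame, invisibly if `output` is written.
#' @export
run_effect_pipeline <- function(input, output = NULL, types = "all",
                                group_col = "sex",
                                trait_cols = c("fat_mass", "heart_weight"),
                                stratum_cols = c("center", "strain"),
                                group_order = NULL, dep = dependence_spec()) {
  st <- read_study_table(input, group_col, trait_cols, stratum_cols)
  eff <- effect_table(st, types = types, group_order = group_order, dep = dep)
  if (all(is.na(eff$estimate))) {
    md_stop("momentdiff_invalid_input",
            sprintf("all %d effect rows failed; first reason: %s",
                    nrow(eff), eff$reason[1]))
  }
  if (!is.null(output)) {
    write_effect_csv(eff, output)
    return(invisible(eff))
  }
  eff
}

#' Effect-size CSV -> pooled meta-analytic summary
#'
#' Reads the effect-size CSV, pools each effect kind (and, for moment
#' contrasts, each trait) separately with [random_effects_meta()], and writes
#' a one-row-per-model summary CSV. Rows with missing estimates are dropped
#' with a message. With `weighting = "auto"`, `delta_ku` models use
#' sample-size weights and all others inverse-variance REML.
#'
#' @param input Path to the effect-size CSV (or a data.frame in that schema).
#' @param output Path for the summary CSV (NULL to skip writing).
#' @param random_factors Stratum columns to use as crossed random factors.
#' @param weighting `"auto"`, `"inverse_variance"`, or `"sample_size"`.
#' @param level Confidence level.
#' @return Data.frame with one row per fitted model.
#' @export
run_meta_pipeline <- function(input, output = NULL, random_factors = NULL,
                              weighting = "auto", level = 0.95) {
  eff <- if (is.data.frame(input)) input else read_effect_csv(input)
  dropped <- sum(!is.finite(eff$estimate) | !is.finite(eff$sampling_variance))
  if (dropped > 0) {
    message(sprintf("dropping %d effect row(s) with missing estimate or variance", dropped))
    eff <- eff[is.finite(eff$estimate) & is.finite(eff$sampling_variance), , drop = FALSE]
  }
  if (nrow(eff) == 0) invalid_input("no usable effect rows")
  groups <- if ("trait" %in% names(eff)) {
    split(eff, list(eff$effect_kind, eff$trait), drop = TRUE)
  } else {
    split(eff, eff$effect_kind, drop = TRUE)
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    fit <- random_effects_meta(g, random_factors = random_factors,
                               weighting = weighting, level = level)
    res <- as.data.frame(fit)
    if ("trait" %in% names(g)) res$trait <- g$trait[1]
    res$k_dropped <- 0L
    res
  }))
  rownames(out) <- NULL
  if (!is.null(output)) {
    utils::write.csv(out, output, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Read a simulation configuration file
#'
#' YAML or JSON file with any of the keys `families`, `n_set`, `sk_values`,
#' `ku_values`, `r_values`, `variance_conditions`, `mean_conditions`,
#' `reps`, `seed`. Unknown keys are a configuration error.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return Named list of settings.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("families", "n_set", "sk_values", "ku_values", "r_values",
               "variance_conditions", "mean_conditions", "reps", "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0) {
    config_error(sprintf("unknown config key(s): %s (allowed: %s)",
                         paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  cfg
}

#' Simulation study pipeline
#'
#' Builds the scenario grid from a config (file path or list), prints the
#' scenario counts, and -- unless `dry_run` -- runs the study and writes the
#' performance CSV.
#'
#' @param config Path to a YAML/JSON config, a list of [build_scenarios()]
#'   arguments (plus optional `reps`, `seed`), or NULL for the full default
#'   grid.
#' @param output Performance CSV path (NULL to skip writing).
#' @param reps,seed Overrides for the config values (defaults 2500 and 1).
#' @param dry_run If TRUE, only print and return the scenario counts.
#' @param cache_dir,progress Passed to [run_study()].
#' @return The performance table, or (for `dry_run`) the scenario table.
#' @export
run_simulation_pipeline <- function(config = NULL, output = NULL, reps = NULL,
                                    seed = NULL, dry_run = FALSE,
                                    cache_dir = NULL, progress = 0) {
  cfg <- if (is.null(config)) list() else if (is.character(config)) read_sim_config(config) else config
  reps <- reps %||% cfg$reps %||% 2500
  seed <- seed %||% cfg$seed %||% 1
  cfg$reps <- NULL; cfg$seed <- NULL
  scen <- do.call(build_scenarios, cfg)
  counts <- table(scen$family)
  message(sprintf("scenario grid: %d cells (%s)", nrow(scen),
                  paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")))
  if (dry_run) return(invisible(scen))
  run_study(scen, reps = reps, root_seed = seed, cache_dir = cache_dir,
            csv = output, progress = progress)
}

#' Fig-2-style performance panels
#'
#' Plots a performance metric against group sample size, one line per
#' scenario, faceted by family, in the layout used to summarize the
#' simulation study.
#'
#' @param perf Performance table from [run_study()].
#' @param metric One of `"bias"`, `"rel_var_bias"`, `"coverage"`.
#' @param pairing Estimator pairing to display (see
#'   `momentdiff:::estimator_pairings()` for the four names).
#' @return A ggplot object.
#' @export
plot_performance <- function(perf, metric = c("bias", "rel_var_bias", "coverage"),
                             pairing = "analytic_jackknife") {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    md_stop("momentdiff_config_error", "plot_performance requires the ggplot2 package")
  }
  d <- perf[perf$estimator_pairing == pairing, , drop = FALSE]
  if (nrow(d) == 0) config_error(sprintf("no rows for estimator pairing '%s'", pairing))
  d$cell <- sub("_n=\\d+$", "", d$scenario_id)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data[[metric]],
                                       group = .data$cell)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::facet_wrap(~family, scales = "free_y") +
    ggplot2::labs(x = "group sample size", y = metric,
                  title = sprintf("%s (%s)", metric, pairing)) +
    ggplot2::theme_minimal()
  if (metric == "coverage") {
    p <- p + ggplot2::geom_hline(yintercept = 0.95, linetype = 2)
  }
  p
}
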