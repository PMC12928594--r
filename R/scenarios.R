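# Scenario grids for the Monte-Carlo study. Three families:
#   skew: Pearson draws, kurtosis fixed at 3, skewness varied per group;
#   kurt: skewness fixed at 0, kurtosis varied per group;
#   zr:   bivariate normal pairs, within-group correlation varied per group.
# Moment families cross each ordered (g1, g2) pair with two variance
# conditions (1 vs 1, or 2 vs 1) and two mean conditions (0 vs 0, or 0 vs 5),
# giving 5^2 * 2 * 2 = 100 scenarios per sample size (1,200 cells over the
# default 12 sample sizes); the zr family has 8^2 = 64 ordered pairs per
# sample size (768 cells).

default_n_set <- function() c(seq(10L, 100L, by = 10L), 150L, 500L)

#' Enumerate simulation scenarios
#'
#' Builds the deterministic, sorted scenario table for the Monte-Carlo study.
#' Default grids: skewness values \{-1, -0.5, 0, 0.5, 1\} (kurtosis 3),
#' kurtosis values \{2.5, 3, 4, 5, 6\} (skewness 0), correlations
#' \{-0.8, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.8\}, group sizes
#' \{10, 20, ..., 100, 150, 500\}, and for the moment families equal/different
#' variance (1 vs 2) and mean (0 vs 5) conditions crossed.
#'
#' @param families Subset of `c("skew", "kurt", "zr")`.
#' @param n_set Integer vector of per-group sample sizes.
#' @param sk_values,ku_values,r_values Per-family grid values.
#' @param variance_conditions,mean_conditions Subsets of
#'   `c("equal", "different")` for the moment families.
#' @return A data.frame with one row per scenario cell: `scenario_id`,
#'   `family`, `n`, group parameter columns, and the true effect `truth`.
#' @examples
#' nrow(build_scenarios("zr")) # 768
#' @export
build_scenarios <- function(families = c("skew", "kurt", "zr"),
                            n_set = default_n_set(),
                            sk_values = c(-1, -0.5, 0, 0.5, 1),
                            ku_values = c(2.5, 3, 4, 5, 6),
                            r_values = c(-0.8, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.8),
                            variance_conditions = c("equal", "different"),
                            mean_conditions = c("equal", "different")) {
  families <- match.arg(families, c("skew", "kurt", "zr"), several.ok = TRUE)
  if (length(n_set) < 1 || anyNA(n_set) || any(n_set < 5) || any(n_set != floor(n_set))) {
    config_error("n_set must be integers >= 5")
  }
  bad_cond <- setdiff(c(variance_conditions, mean_conditions), c("equal", "different"))
  if (length(bad_cond) > 0) {
    config_error(sprintf("unknown condition value(s): %s", paste(bad_cond, collapse = ", ")))
  }
  if (anyNA(r_values) || any(abs(r_values) > 1)) config_error("r_values must lie in [-1, 1]")

  out <- list()
  moment_family <- function(family, values) {
    g <- expand.grid(n = sort(unique(n_set)),
                     mean_cond = sort(unique(mean_conditions)),
                     var_cond = sort(unique(variance_conditions)),
                     g2 = sort(unique(values)), g1 = sort(unique(values)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(
      scenario_id = sprintf("%s_g1=%g_g2=%g_v=%s_m=%s_n=%d", family, g$g1, g$g2,
                            substr(g$var_cond, 1, 3), substr(g$mean_cond, 1, 3), g$n),
      family = family,
      n = as.integer(g$n),
      mean1 = 0, mean2 = ifelse(g$mean_cond == "equal", 0, 5),
      var1 = 1, var2 = ifelse(g$var_cond == "equal", 1, 2),
      sk1 = if (family == "skew") g$g1 else 0,
      sk2 = if (family == "skew") g$g2 else 0,
      ku1 = if (family == "kurt") g$g1 else 3,
      ku2 = if (family == "kurt") g$g2 else 3,
      r1 = NA_real_, r2 = NA_real_,
      truth = g$g1 - g$g2, # excess-scale offsets cancel for the kurt family
      stringsAsFactors = FALSE
    )
  }
  if ("skew" %in% families) {
    infeasible <- abs(sk_values)^2 + 1 >= 3
    if (any(infeasible)) {
      config_error(sprintf("skewness value(s) %s infeasible at kurtosis 3",
                           paste(sk_values[infeasible], collapse = ", ")))
    }
    out$skew <- moment_family("skew", sk_values)
  }
  if ("kurt" %in% families) {
    if (any(ku_values <= 1)) config_error("kurtosis values must exceed 1")
    k <- moment_family("kurt", ku_values)
    k$truth <- k$ku1 - k$ku2
    out$kurt <- k
  }
  if ("zr" %in% families) {
    g <- expand.grid(n = sort(unique(n_set)),
                     r2 = sort(unique(r_values)), r1 = sort(unique(r_values)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$zr <- data.frame(
      scenario_id = sprintf("zr_r1=%g_r2=%g_n=%d", g$r1, g$r2, g$n),
      family = "zr",
      n = as.integer(g$n),
      mean1 = 0, mean2 = 0, var1 = 1, var2 = 1,
      sk1 = 0, sk2 = 0, ku1 = 3, ku2 = 3,
      r1 = g$r1, r2 = g$r2,
      truth = atanh(g$r1) - atanh(g$r2),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[order(names(out))])
  rownames(res) <- NULL
  res[order(res$scenario_id), , drop = FALSE]
}
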