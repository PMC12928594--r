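# Random-effects pooling of effect sizes. Inverse-variance weighting fits a
# multilevel REML model through metafor (rma.uni for the plain model, rma.mv
# for crossed random factors); sample-size weighting (recommended for
# delta_ku, whose analytic sampling variance is unreliable) uses effective-n
# weights with a moment-based tau^2 and a weighted-residual pooled SE.

effects_input_table <- function(effects) {
  if (inherits(effects, "effect_size")) effects <- list(effects)
  if (is.list(effects) && !is.data.frame(effects) &&
      all(vapply(effects, inherits, logical(1), "effect_size"))) {
    effects <- effects_to_table(effects)
  }
  if (!is.data.frame(effects) || nrow(effects) < 1) {
    invalid_input("effects must be effect_size objects or a data.frame in the effect-size schema")
  }
  need <- c("effect_kind", "estimate", "sampling_variance", "n1", "n2")
  missing_cols <- setdiff(need, names(effects))
  if (length(missing_cols) > 0) {
    invalid_input(sprintf("effect table is missing column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  }
  kinds <- unique(effects$effect_kind)
  if (length(kinds) > 1) {
    invalid_input(sprintf("all effects must share one effect_kind; got: %s",
                          paste(kinds, collapse = ", ")))
  }
  if (anyNA(effects$estimate)) invalid_input("effect table contains missing estimates")
  effects
}

typical_sampling_variance <- function(v) {
  # "typical" within-effect variance entering I^2 (Higgins-style, extended to
  # multilevel decompositions)
  w <- 1 / v
  k <- length(v)
  (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

new_meta_result <- function(pooled, se, level, tau2_components, k, weighting,
                            effect_kind, s2_typical, note = NULL) {
  z <- stats::qnorm((1 + level) / 2)
  tau2_total <- sum(tau2_components)
  denom <- tau2_total + s2_typical
  i2_components <- if (denom > 0) 100 * tau2_components / denom else tau2_components * 0
  structure(
    list(
      effect_kind = effect_kind,
      pooled_estimate = pooled,
      pooled_se = se,
      ci = c(lower = pooled - z * se, upper = pooled + z * se),
      level = level,
      tau2_components = tau2_components,
      s2_typical = s2_typical,
      i2_components = i2_components,
      i2_total = sum(i2_components),
      k = k,
      weighting = weighting,
      note = note
    ),
    class = "meta_result"
  )
}

#' Random-effects meta-analysis of a set of effect sizes
#'
#' Pools effects sharing one `effect_kind`. With `weighting =
#' "inverse_variance"` the model is an intercept-only multilevel
#' random-effects model estimated by REML (via \pkg{metafor}): the supplied
#' `random_factors` (e.g., phenotyping center, strain) become additive
#' variance components, plus an observation-level "effect_id" component
#' (between-effect heterogeneity). With `weighting = "sample_size"` --
#' recommended for `delta_ku`, whose sampling-variance estimators are
#' unreliable -- weights are the effective sample sizes \eqn{\tilde n =
#' n_1n_2/(n_1+n_2)}; \eqn{\tau^2} comes from a generalized
#' DerSimonian--Laird moment estimator on the n-weighted residuals (it reduces
#' to classic DL when \eqn{w = 1/v}), and the pooled SE from the weighted
#' residuals, \eqn{\sqrt{\sum w_i^2 (y_i - \bar y_w)^2}/\sum w_i}, which does
#' not trust the reported sampling variances.
#'
#' @param effects `effect_size` objects (list or single) or a data.frame in
#'   the schema written by [effects_to_table()], optionally with extra factor
#'   columns.
#' @param random_factors Character vector of column names to use as crossed
#'   random factors (inverse-variance path only).
#' @param weighting `"auto"` (sample-size for `delta_ku`, inverse-variance
#'   otherwise), `"inverse_variance"`, or `"sample_size"`.
#' @param level Confidence level for the Wald CI of the pooled effect.
#' @return A `meta_result`: pooled estimate, SE, CI, per-component
#'   \eqn{\tau^2} and \eqn{I^2} (percent), total \eqn{I^2}, `k`, weighting.
#' @examples
#' es <- lapply(1:6, function(i) effect_from_summaries("delta_zr", 0.5, 0.3, 100, 100))
#' random_effects_meta(es)
#' @export
random_effects_meta <- function(effects, random_factors = NULL,
                                weighting = c("auto", "inverse_variance", "sample_size"),
                                level = 0.95) {
  weighting <- match.arg(weighting)
  tab <- effects_input_table(effects)
  kind <- tab$effect_kind[1]
  if (weighting == "auto") {
    weighting <- if (kind == "delta_ku") "sample_size" else "inverse_variance"
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) invalid_input("level must be in (0, 1)")
  k <- nrow(tab)
  y <- tab$estimate
  v <- tab$sampling_variance
  if (any(!is.finite(v)) || any(v <= 0)) {
    invalid_input("all sampling variances must be positive and finite")
  }

  if (k == 1) {
    return(new_meta_result(y, sqrt(v), level,
                           c(effect_id = 0), 1L, weighting, kind, v,
                           note = "single effect: pooled result is the input effect, tau^2 = 0"))
  }

  if (weighting == "sample_size") {
    w <- effective_n(tab$n1, tab$n2)
    sw <- sum(w)
    yw <- sum(w * y) / sw
    res <- y - yw
    q_w <- sum(w * res^2)
    denom <- sw - sum(w^2) / sw
    expected_q0 <- sum(w * v) - sum(w^2 * v) / sw
    tau2 <- max(0, (q_w - expected_q0) / denom)
    se <- sqrt(sum(w^2 * res^2)) / sw
    return(new_meta_result(yw, se, level, c(total = tau2), k, "sample_size",
                           kind, typical_sampling_variance(v)))
  }

  # inverse-variance REML path
  factors <- random_factors %||% character(0)
  missing_cols <- setdiff(factors, names(tab))
  if (length(missing_cols) > 0) {
    invalid_input(sprintf("random factor column(s) not found: %s",
                          paste(missing_cols, collapse = ", ")))
  }
  if (!"effect_id" %in% names(tab)) tab$effect_id <- sprintf("es%03d", seq_len(k))
  factors <- union(factors, "effect_id")
  fit <- tryCatch(
    {
      if (identical(factors, "effect_id")) {
        f <- metafor::rma.uni(yi = y, vi = v, method = "REML", test = "z")
        list(b = as.numeric(f$beta), se = f$se, sigma2 = stats::setNames(f$tau2, "effect_id"))
      } else {
        rnd <- lapply(factors, function(f) stats::as.formula(paste("~ 1 |", f)))
        # near-zero variance components can stall nlminb; fall back to
        # Nelder-Mead before giving up
        f <- tryCatch(
          metafor::rma.mv(yi = y, V = v, random = rnd, data = tab,
                          method = "REML", test = "z", sparse = FALSE),
          error = function(e) {
            metafor::rma.mv(yi = y, V = v, random = rnd, data = tab,
                            method = "REML", test = "z", sparse = FALSE,
                            control = list(optimizer = "optim",
                                           optmethod = "Nelder-Mead"))
          }
        )
        list(b = as.numeric(f$beta), se = f$se, sigma2 = stats::setNames(f$sigma2, factors))
      }
    },
    error = function(e) {
      convergence_error(sprintf("REML fit failed: %s", conditionMessage(e)))
    }
  )
  new_meta_result(fit$b, fit$se, level, fit$sigma2, k, "inverse_variance",
                  kind, typical_sampling_variance(v))
}

#' Heterogeneity decomposition of a fitted meta-analysis
#'
#' Multilevel \eqn{I^2}: each component is \eqn{I^2_\ell = \tau^2_\ell /
#' (\sum_m \tau^2_m + \tilde s^2) \times 100} with \eqn{\tilde s^2} the
#' typical within-effect sampling variance; components sum to the total.
#'
#' @param result A `meta_result` from [random_effects_meta()].
#' @return List with `total` (percent) and named `components`.
#' @export
i_squared <- function(result) {
  stopifnot(inherits(result, "meta_result"))
  list(total = result$i2_total, components = result$i2_components)
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis of %s (k = %d, %s weighting)\n  pooled = %.4f (SE %.4f), %g%% CI %.4f to %.4f\n",
    x$effect_kind, x$k, x$weighting, x$pooled_estimate, x$pooled_se,
    100 * x$level, x$ci[1], x$ci[2]
  ))
  comp <- paste(sprintf("%s: tau2 %.4g (I2 %.1f%%)", names(x$tau2_components),
                        x$tau2_components, x$i2_components), collapse = "; ")
  cat(sprintf("  heterogeneity: %s; I2 total %.1f%%\n", comp, x$i2_total))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
as.data.frame.meta_result <- function(x, ...) {
  out <- data.frame(
    effect_kind = x$effect_kind,
    k = x$k,
    weighting = x$weighting,
    pooled_estimate = x$pooled_estimate,
    pooled_se = x$pooled_se,
    ci_lower = x$ci[1],
    ci_upper = x$ci[2],
    level = x$level,
    tau2_total = sum(x$tau2_components),
    i2_total = x$i2_total,
    stringsAsFactors = FALSE
  )
  for (nm in names(x$tau2_components)) {
    out[[paste0("tau2_", nm)]] <- x$tau2_components[[nm]]
    out[[paste0("i2_", nm)]] <- x$i2_components[[nm]]
  }
  rownames(out) <- NULL
  out
}
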