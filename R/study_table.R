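# Ingestion of long-format individual-level data (one row per individual:
# group label, one or two trait columns, optional stratum columns) and the
# per-stratum effect-size pipeline.

#' Read a long-format two-group study table
#'
#' Reads a delimited file (comma-separated, UTF-8, '.' decimal) with a header
#' and validates the column mapping. Rows with unparseable or missing trait
#' values are kept in the table (they are dropped, and counted, per contrast
#' when group samples are built); rows with a missing group label are dropped
#' here. Exactly two distinct group labels must remain.
#'
#' @param path CSV file path, or a data.frame already in memory.
#' @param group_col Name of the group-label column.
#' @param trait_cols One or two trait column names (two for correlation-based
#'   contrasts).
#' @param stratum_cols Optional stratum column names (e.g., center, strain);
#'   effects are computed separately per stratum combination.
#' @return A `study_table`: list with `data`, the column mapping, the two
#'   `group_levels`, and `n_bad_trait` (trait cells that failed to parse).
#' @export
read_study_table <- function(path, group_col, trait_cols, stratum_cols = character(0)) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) config_error(sprintf("input file not found: %s", path))
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  needed <- c(group_col, trait_cols, stratum_cols)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    config_error(sprintf("mapped column(s) not present in table: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (length(trait_cols) < 1 || length(trait_cols) > 2) {
    config_error("trait_cols must name one or two columns")
  }
  df <- df[!is.na(df[[group_col]]) & df[[group_col]] != "", , drop = FALSE]
  n_bad <- 0L
  for (tc in trait_cols) {
    parsed <- suppressWarnings(as.numeric(df[[tc]]))
    n_bad <- n_bad + sum(is.na(parsed) & !is.na(df[[tc]]))
    df[[tc]] <- parsed
  }
  groups <- sort(unique(as.character(df[[group_col]])))
  if (length(groups) != 2) {
    invalid_input(sprintf("expected exactly 2 group labels, found %d: %s",
                          length(groups), paste(groups, collapse = ", ")))
  }
  structure(
    list(data = df, group_col = group_col, trait_cols = trait_cols,
         stratum_cols = stratum_cols, group_levels = groups, n_bad_trait = n_bad),
    class = "study_table"
  )
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf(
    "Study table: %d rows, groups %s vs %s, trait(s) %s%s\n",
    nrow(x$data), x$group_levels[1], x$group_levels[2],
    paste(x$trait_cols, collapse = " + "),
    if (length(x$stratum_cols) > 0) paste0(", strata by ", paste(x$stratum_cols, collapse = " x ")) else ""
  ))
  if (x$n_bad_trait > 0) cat(sprintf("  %d trait cells failed to parse (treated as missing)\n", x$n_bad_trait))
  tab <- table(do.call(paste, c(x$data[c(x$stratum_cols, x$group_col)], sep = "/")))
  print(tab)
  invisible(x)
}

effect_kinds_cli <- c(dsk = "delta_sk", dku = "delta_ku", dzr = "delta_zr",
                      lnrr = "lnRR", lnvr = "lnVR")

compute_one_effect <- function(kind, g1, g2, dep, warn_small_n) {
  switch(kind,
    delta_sk = delta_skewness(g1, g2, dep, warn_small_n = warn_small_n),
    delta_ku = delta_kurtosis(g1, g2, dep, warn_small_n = warn_small_n),
    delta_zr = delta_zr(g1, g2, dep),
    lnRR = lnRR(g1, g2),
    lnVR = lnVR(g1, g2)
  )
}

#' Compute effect sizes per stratum from a study table
#'
#' Splits the table by the stratum columns and, within each stratum, contrasts
#' the two groups for the requested effect types. Moment contrasts and
#' lnRR/lnVR are computed per trait column; `delta_zr` uses the two trait
#' columns as the within-group pair. Strata where a statistic is undefined
#' produce a row with NA estimate and a `reason` code instead of failing the
#' whole run.
#'
#' @param st A `study_table` from [read_study_table()].
#' @param types Effect types: any of `"dsk"`, `"dku"`, `"dzr"`, `"lnrr"`,
#'   `"lnvr"`, or `"all"`.
#' @param group_order Optional length-2 character vector naming which group
#'   label is group 1 (first) and group 2; defaults to alphabetical order.
#'   Positive estimates mean group 1 exceeds group 2.
#' @param dep A [dependence_spec()].
#' @param warn_small_n Warn for moment contrasts on groups below n = 50.
#' @return A data.frame: one row per stratum x trait x effect type, in the
#'   stable effect-size schema plus `trait`, stratum tags, and `reason`.
#' @export
effect_table <- function(st, types = "all", group_order = NULL,
                         dep = dependence_spec(), warn_small_n = TRUE) {
  stopifnot(inherits(st, "study_table"))
  if ("all" %in% types) types <- names(effect_kinds_cli)
  bad <- setdiff(types, names(effect_kinds_cli))
  if (length(bad) > 0) {
    config_error(sprintf("unknown effect type(s): %s (use %s)",
                         paste(bad, collapse = ", "),
                         paste(names(effect_kinds_cli), collapse = ", ")))
  }
  kinds <- unname(effect_kinds_cli[types])
  g_order <- group_order %||% st$group_levels
  if (!setequal(g_order, st$group_levels) || length(g_order) != 2) {
    config_error(sprintf("group_order must be a permutation of: %s",
                         paste(st$group_levels, collapse = ", ")))
  }
  df <- st$data
  strata <- if (length(st$stratum_cols) > 0) {
    split(df, df[st$stratum_cols], drop = TRUE)
  } else {
    list(all = df)
  }

  rows <- list()
  for (s_name in names(strata)) {
    sd_ <- strata[[s_name]]
    tags <- if (length(st$stratum_cols) > 0) {
      as.list(sd_[1, st$stratum_cols, drop = FALSE])
    } else {
      list()
    }
    d1 <- sd_[sd_[[st$group_col]] == g_order[1], , drop = FALSE]
    d2 <- sd_[sd_[[st$group_col]] == g_order[2], , drop = FALSE]
    for (kind in kinds) {
      trait_sets <- if (kind == "delta_zr") {
        if (length(st$trait_cols) != 2) {
          config_error("delta_zr requires two trait columns")
        }
        list(paste(st$trait_cols, collapse = "+"))
      } else {
        as.list(st$trait_cols)
      }
      for (tr in trait_sets) {
        res <- tryCatch(
          {
            if (kind == "delta_zr") {
              g1 <- group_sample(d1[[st$trait_cols[1]]], d1[[st$trait_cols[2]]], g_order[1])
              g2 <- group_sample(d2[[st$trait_cols[1]]], d2[[st$trait_cols[2]]], g_order[2])
            } else {
              g1 <- group_sample(d1[[tr]], label = g_order[1])
              g2 <- group_sample(d2[[tr]], label = g_order[2])
            }
            e <- compute_one_effect(kind, g1, g2, dep, warn_small_n)
            out <- as.data.frame(e)
            out$reason <- NA_character_
            out
          },
          momentdiff_error = function(e) {
            data.frame(effect_kind = kind, estimate = NA_real_,
                       sampling_variance = NA_real_,
                       n1 = sum(is.finite(d1[[st$trait_cols[1]]])),
                       n2 = sum(is.finite(d2[[st$trait_cols[1]]])),
                       point_method = NA_character_, variance_method = NA_character_,
                       reason = conditionMessage(e), stringsAsFactors = FALSE)
          }
        )
        res$trait <- tr
        for (nm in names(tags)) res[[nm]] <- tags[[nm]]
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  lead <- c("effect_kind", "trait", "estimate", "sampling_variance", "n1", "n2",
            "point_method", "variance_method")
  out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
}

#' Write / read the effect-size CSV schema
#'
#' Plain CSV with a stable leading column order; `read_effect_csv` validates
#' that the mandatory columns are present so downstream meta-analysis fails
#' early on foreign files.
#'
#' @param effects Effect-size data.frame (e.g., from [effect_table()] or
#'   [effects_to_table()]) or a list of `effect_size` objects.
#' @param path CSV path.
#' @return `read_effect_csv` returns the validated data.frame.
#' @export
write_effect_csv <- function(effects, path) {
  if (!is.data.frame(effects)) effects <- effects_to_table(effects)
  utils::write.csv(effects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effect_csv
#' @export
read_effect_csv <- function(path) {
  if (!file.exists(path)) config_error(sprintf("effect CSV not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("effect_kind", "estimate", "sampling_variance", "n1", "n2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    config_error(sprintf("effect CSV is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  df
}
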