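#' Raw observations for one group
#'
#' Container for the per-group data on which moments and correlations are
#' computed. Missing values are dropped at construction (pairwise when a
#' second trait is present) and the number of dropped rows is recorded so
#' pipelines can report exclusions.
#'
#' @param values Numeric vector of observations for the first (or only) trait.
#' @param second_values Optional numeric vector, parallel to `values`, for the
#'   second trait (correlation-based effect sizes).
#' @param label Free-text group identifier used in error messages and output.
#' @return A `group_sample`: list with `values`, `second_values` (or NULL),
#'   `label`, `n`, and `n_dropped`.
#' @examples
#' group_sample(rnorm(50), label = "female")
#' @export
group_sample <- function(values, second_values = NULL, label = "group") {
  if (!is.numeric(values)) invalid_input("group_sample: values must be numeric")
  if (!is.null(second_values)) {
    if (!is.numeric(second_values)) invalid_input("group_sample: second_values must be numeric")
    if (length(second_values) != length(values)) {
      invalid_input(sprintf(
        "group_sample '%s': paired traits of unequal length (%d vs %d)",
        label, length(values), length(second_values)
      ))
    }
    keep <- is.finite(values) & is.finite(second_values)
    dropped <- sum(!keep)
    values <- values[keep]
    second_values <- second_values[keep]
  } else {
    keep <- is.finite(values)
    dropped <- sum(!keep)
    values <- values[keep]
  }
  structure(
    list(
      values = values,
      second_values = second_values,
      label = as.character(label)[1],
      n = length(values),
      n_dropped = dropped
    ),
    class = "group_sample"
  )
}

#' @export
print.group_sample <- function(x, ...) {
  cat(sprintf(
    "Group '%s': n = %d%s%s\n", x$label, x$n,
    if (!is.null(x$second_values)) " (paired traits)" else "",
    if (x$n_dropped > 0) sprintf(", %d rows dropped (missing)", x$n_dropped) else ""
  ))
  invisible(x)
}

as_group_sample <- function(g, paired = FALSE) {
  if (!inherits(g, "group_sample")) invalid_input("expected a group_sample object")
  if (paired && is.null(g$second_values)) {
    invalid_input(sprintf("group '%s' carries no second trait; paired data required", g$label))
  }
  g
}
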