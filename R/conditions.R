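# Typed conditions so pipelines can count and report exclusions instead of
# swallowing NaN/0. All inherit "momentdiff_error".

md_stop <- function(class, msg, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "momentdiff_error", "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cond)
}

invalid_input <- function(msg) md_stop("momentdiff_invalid_input", msg)

undefined_statistic <- function(msg) md_stop("momentdiff_undefined_statistic", msg)

domain_error <- function(msg) md_stop("momentdiff_domain_error", msg)

config_error <- function(msg) md_stop("momentdiff_config_error", msg)

convergence_error <- function(msg) md_stop("momentdiff_convergence_error", msg)

# Warning used when a group is below the recommended n for moment contrasts.
small_n_warning <- function(msg) {
  warning(structure(
    class = c("momentdiff_small_n", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Re-raise a momentdiff error with a group label prefixed, keeping the class.
with_group_label <- function(expr, label) {
  withCallingHandlers(
    expr,
    momentdiff_error = function(e) {
      e$message <- sprintf("[group %s] %s", label, conditionMessage(e))
      stop(e)
    }
  )
}
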