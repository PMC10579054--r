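new_ho_test <- function(method, statistic = NA_real_, p_value = NA_real_,
                        estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        conf_level = NA_real_, flags = character(), ...) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    abort("p-value outside [0, 1]")
  }
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 conf_level = conf_level, flags = flags, ...),
            class = "ho_test")
}

#' @export
print.ho_test <- function(x, ...) {
  cat(sprintf("<ho_test> %s\n", x$method))
  if (!is.na(x$estimate)) {
    ci <- if (!is.na(x$ci_low)) sprintf(" (%d%% CI %.3g, %.3g)",
                                        round(100 * x$conf_level), x$ci_low, x$ci_high) else ""
    cat(sprintf("  estimate %.4g%s\n", x$estimate, ci))
  }
  if (!is.na(x$statistic)) cat(sprintf("  statistic %.4g\n", x$statistic))
  if (!is.na(x$p_value)) cat(sprintf("  p-value %.4g\n", x$p_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a hypothesis-test result
#'
#' @param x An `ho_test`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `estimate`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high` and any flags collapsed to a string.
#' @export
tidy.ho_test <- function(x, ...) {
  tibble(method = x$method, estimate = x$estimate, statistic = x$statistic,
         p.value = x$p_value, conf.low = x$ci_low, conf.high = x$ci_high,
         flags = paste(x$flags, collapse = ";"))
}

#' @rdname tidy.ho_test
#' @export
glance.ho_test <- function(x, ...) tidy.ho_test(x, ...)
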