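#' Plot a gatekeeping hierarchy
#'
#' P-values by hierarchy position on a log scale, with the significance
#' level as a dashed line; untested hypotheses are hollow.
#'
#' @param object An `ho_gatekeeping` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ho_gatekeeping <- function(object, ...) {
  alpha <- attr(object, "alpha")
  df <- as_tibble(object)
  df$outcome <- dplyr::case_when(!df$tested ~ "untested",
                                 df$significant ~ "significant",
                                 TRUE ~ "not significant")
  ggplot2::ggplot(df, ggplot2::aes(.data$order, .data$p_value)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$outcome), size = 3) +
    ggplot2::scale_shape_manual(values = c(significant = 16,
                                           `not significant` = 4,
                                           untested = 1)) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_x_continuous(breaks = df$order, labels = df$label) +
    ggplot2::labs(x = NULL, y = "p-value",
                  title = sprintf("fixed-sequence hierarchy (alpha = %g)", alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot new-lesion burden by arm and period
#'
#' Observed new-lesion rates (lesions/patient) per arm and period from a
#' pipeline run, the quantity the crossover comparison works on.
#'
#' @param object An `ho_run` from [run_ho_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ho_run <- function(object, ...) {
  df <- object$summary
  df$period <- factor(df$period, labels = c("period 1", "period 2"))
  ggplot2::ggplot(df, ggplot2::aes(.data$period, .data$observed_rate,
                                   fill = .data$arm)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "observed new CT lesions / patient",
                  fill = "arm (period 1)",
                  title = "new-lesion rate by arm and period") +
    ggplot2::theme_minimal()
}
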