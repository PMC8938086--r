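#' Plot per-grade imaging-feature frequencies
#'
#' Stacked proportion bars per differentiation grade, one facet per imaging
#' feature — the standard way to eyeball how the malignant-leaning feature
#' frequencies shift with differentiation.
#'
#' @param object A [feature_frequency_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_frequency_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$grade, y = .data$prop,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = "Differentiation grade", y = "Proportion of lesions",
                  fill = "Category") +
    ggplot2::theme_minimal()
}

#' Plot marker positivity by tissue group
#'
#' @param object An [expression_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expression_table <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(rate = .data$positive / (.data$positive + .data$negative))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Tissue group", y = "Positive expression rate") +
    ggplot2::theme_minimal()
}

#' Plot diagnostic performance across examination arms
#'
#' Grouped bars of sensitivity, specificity and accuracy per arm, as
#' returned in the `diagnosis` element of [run_pipeline()] or built from
#' [glance()] rows.
#'
#' @param diagnosis Tibble with columns `group`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @return A ggplot object.
#' @export
plot_diagnostic_performance <- function(diagnosis) {
  long <- diagnosis |>
    dplyr::select("group", "sensitivity", "specificity", "accuracy") |>
    tidyr::pivot_longer(-"group", names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Examination arm", y = "Value", fill = NULL) +
    ggplot2::theme_minimal()
}
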