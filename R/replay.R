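#' Reference diagnosis-versus-pathology tables
#'
#' The four printed 2x2 contingency blocks (one per examination arm) from
#' the reference four-arm study of multimodal ultrasound in small liver
#' cancer, shipped as a packaged fixture so the diagnostic statistics can be
#' recomputed offline. Cells are counts of lesions called malignant/benign
#' against pathology.
#'
#' @return Tibble with columns `group`, `tp`, `fp`, `fn`, `tn`.
#' @export
reference_diagnosis_tables <- function() {
  tibble(
    group = c("doppler", "contrast", "elastic", "multimodal"),
    tp = c(16, 18, 16, 24),
    fp = c(4, 3, 3, 1),
    fn = c(10, 13, 10, 3),
    tn = c(8, 6, 7, 10)
  )
}

#' Reference reported diagnostic statistics
#'
#' The sensitivity, specificity, accuracy and kappa values printed alongside
#' the reference contingency tables. Several printed values are not
#' arithmetically consistent with the printed cells (see
#' [replay_reference_tables()], which flags them); they are shipped verbatim
#' for comparison, not as derived truth.
#'
#' @return Tibble with columns `group`, `sensitivity_pct`, `specificity_pct`,
#'   `accuracy_pct`, `kappa`.
#' @export
reference_reported_performance <- function() {
  tibble(
    group = c("doppler", "contrast", "elastic", "multimodal"),
    sensitivity_pct = c(57.69, 58.06, 61.54, 88.87),
    specificity_pct = c(66.67, 66.67, 70.00, 90.91),
    accuracy_pct = c(63.16, 60.00, 63.89, 89.47),
    kappa = c(0.46, 0.49, 0.48, 0.68)
  )
}

#' Reference marker expression count tables
#'
#' Printed EZH2 and p57 negative/positive specimen counts for the lesional,
#' perilesional and normal-liver tissue groups, with the printed positive
#' rates where the source states them. Note two known internal
#' inconsistencies of the source, shipped as printed: the p57 lesional row
#' sums to 83 although the stated group size is 79, and its printed rate
#' (40.04%) matches neither reading of the counts.
#'
#' @return Tibble with columns `marker`, `group`, `negative`, `positive`,
#'   `reported_rate_pct` (`NA` where no rate was printed).
#' @export
reference_expression_tables <- function() {
  tibble(
    marker = rep(c("EZH2", "p57"), each = 3),
    group = rep(c("lesional", "perilesional", "normal"), 2),
    negative = c(19, 67, 35, 49, 16, 2),
    positive = c(60, 12, 4, 34, 63, 37),
    reported_rate_pct = c(75.95, 15.19, 10.26, 40.04, 79.75, 94.87)
  )
}

#' Recompute every derivable statistic from the reference tables
#'
#' Recomputes sensitivity/specificity/accuracy/kappa from the printed
#' contingency cells and positive rates from the printed expression counts,
#' places them side by side with the printed values, and flags every
#' disagreement at the printed 2-decimal precision. This is the package's
#' regression surface: the arithmetically consistent printed values must
#' reproduce exactly, and the known-inconsistent ones must be flagged, not
#' silently matched.
#'
#' @return A list of two tibbles. `$diagnosis`: per group and statistic,
#'   `computed`, `reported`, `discrepancy`. `$expression`: per marker and
#'   tissue group, `computed_rate_pct`, `reported_rate_pct`, `discrepancy`.
#' @examples
#' rep <- replay_reference_tables()
#' dplyr::filter(rep$diagnosis, discrepancy)
#' @export
replay_reference_tables <- function() {
  cells <- reference_diagnosis_tables()
  computed <- cells |>
    dplyr::rowwise() |>
    dplyr::mutate(glance(contingency_2x2(.data$tp, .data$fp, .data$fn, .data$tn))) |>
    dplyr::ungroup() |>
    dplyr::mutate(kappa = round_half_up(.data$kappa)) |>
    dplyr::select("group", "sensitivity_pct", "specificity_pct",
                  "accuracy_pct", "kappa") |>
    tidyr::pivot_longer(-"group", names_to = "statistic", values_to = "computed")
  reported <- reference_reported_performance() |>
    tidyr::pivot_longer(-"group", names_to = "statistic", values_to = "reported")
  diagnosis <- dplyr::left_join(computed, reported, by = c("group", "statistic")) |>
    dplyr::mutate(discrepancy = abs(.data$computed - .data$reported) > 0.005)

  expression <- reference_expression_tables() |>
    dplyr::mutate(
      computed_rate_pct = round_half_up(
        100 * .data$positive / (.data$positive + .data$negative)),
      discrepancy = is.na(.data$reported_rate_pct) |
        abs(.data$computed_rate_pct - .data$reported_rate_pct) > 0.005
    ) |>
    dplyr::select("marker", "group", "negative", "positive",
                  "computed_rate_pct", "reported_rate_pct", "discrepancy")

  list(diagnosis = diagnosis, expression = expression)
}
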