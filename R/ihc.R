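#' Semiquantitative immunohistochemistry positivity score
#'
#' Combines a staining-intensity score (0-3) with a positive-cell-percentage
#' score (0-4) by the product rule: a specimen is positive when the product
#' exceeds 3 (strictly; a product of exactly 3 is negative). Vectorised over
#' specimens.
#'
#' @param intensity_score Integer vector in 0..3.
#' @param percent_score Integer vector in 0..4.
#' @param marker Optional marker label carried into the output.
#' @return Tibble with columns `marker`, `intensity_score`, `percent_score`,
#'   `product`, `positive`.
#' @examples
#' score_specimen(2, 2) # product 4: positive
#' score_specimen(1, 3) # product 3: negative
#' @export
score_specimen <- function(intensity_score, percent_score, marker = NA_character_) {
  if (anyNA(intensity_score) || any(intensity_score < 0 | intensity_score > 3) ||
      any(intensity_score != as.integer(intensity_score))) {
    abort("`intensity_score` must be integers in 0..3.")
  }
  if (anyNA(percent_score) || any(percent_score < 0 | percent_score > 4) ||
      any(percent_score != as.integer(percent_score))) {
    abort("`percent_score` must be integers in 0..4.")
  }
  product <- as.integer(intensity_score) * as.integer(percent_score)
  tibble(
    marker = marker,
    intensity_score = as.integer(intensity_score),
    percent_score = as.integer(percent_score),
    product = product,
    positive = product > 3
  )
}

#' Aggregate per-specimen positivity into a group expression table
#'
#' @param specimens Tibble with a grouping column and a logical positivity
#'   column.
#' @param group Name of the grouping column (default `"group"`).
#' @param positive Name of the logical positivity column (default
#'   `"positive"`).
#' @return A tibble of class `expression_table` with columns `group`,
#'   `negative`, `positive` (counts); row sums equal group sizes.
#' @export
expression_table <- function(specimens, group = "group", positive = "positive") {
  specimens <- as_tibble(specimens)
  if (!group %in% names(specimens) || !positive %in% names(specimens)) {
    abort("`specimens` must contain the grouping and positivity columns.")
  }
  out <- specimens |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      negative = sum(!.data[[positive]]),
      positive = sum(.data[[positive]]),
      .groups = "drop"
    )
  class(out) <- c("expression_table", class(out))
  out
}

#' Positive expression rate of one group
#'
#' `positive / (positive + negative)` as a percentage rounded half-up to
#' 2 decimals.
#'
#' @param table An [expression_table()] (columns `group`, `negative`,
#'   `positive`).
#' @param group Group label to extract.
#' @return The percentage, with the raw fraction in attribute `"prop"`.
#' @examples
#' tab <- tibble::tibble(group = "lesional", negative = 19, positive = 60)
#' positive_rate(tab, "lesional") # 75.95
#' @export
positive_rate <- function(table, group) {
  row <- dplyr::filter(as_tibble(table), .data$group == !!group)
  if (nrow(row) != 1) abort(sprintf("Group \"%s\" not found exactly once.", group))
  n <- row$negative + row$positive
  if (n == 0) abort("Empty group row.")
  structure(round_half_up(100 * row$positive / n), prop = row$positive / n)
}

#' Chi-square comparison of expression across groups
#'
#' Tests whether marker positivity differs across the table's groups by a
#' Pearson chi-square on the negative/positive count grid (delegating to
#' [chi_square_test()]).
#'
#' @param table An [expression_table()] with >= 2 groups.
#' @inheritParams chi_square_test
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @export
compare_expression <- function(table, correct = FALSE) {
  table <- as_tibble(table)
  if (nrow(table) < 2) abort("Need at least 2 groups to compare.")
  m <- as.matrix(table[, c("negative", "positive")])
  rownames(m) <- table$group
  chi_square_test(m, correct = correct)
}

#' Positivity rates stratified by differentiation grade
#'
#' Aggregates per-specimen positivity flags carrying a differentiation grade
#' into a per-grade expression table for each marker, with rates.
#'
#' @param specimens Tibble with columns `marker`, `grade`, `positive`; every
#'   specimen must carry a grade.
#' @return A tibble with columns `marker`, `grade`, `negative`, `positive`,
#'   `rate_pct` (half-up, 2 decimals) and `prop`.
#' @export
grade_stratified_rates <- function(specimens) {
  specimens <- as_tibble(specimens)
  if (anyNA(specimens$grade)) abort("Every specimen must carry a grade.")
  specimens |>
    dplyr::group_by(.data$marker, .data$grade) |>
    dplyr::summarise(
      negative = sum(!.data$positive),
      positive = sum(.data$positive),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      prop = .data$positive / (.data$positive + .data$negative),
      rate_pct = round_half_up(100 * .data$prop)
    )
}

#' Configuration for the synthetic immunohistochemistry cohort
#'
#' Defaults emulate the reference tissue groups: 79 lesional specimens
#' ("observation group 1"), 79 perilesional specimens ("observation group
#' 2") and 39 normal-liver controls, with per-group EZH2/p57 positivity
#' probabilities matching the published group rates and per-grade
#' probabilities matching the published grade-stratified rates. The two
#' probability sets are kept independent because the published group-level
#' and grade-level rates are not mutually consistent; group-level sampling
#' is the default, and `stratify_lesional_by_grade = TRUE` switches the
#' lesional specimens to grade-conditional sampling for stratified analyses.
#'
#' @param n_lesional,n_perilesional,n_normal Specimen counts per group.
#' @param group_positive_probabilities Tibble with columns `marker`,
#'   `lesional`, `perilesional`, `normal`.
#' @param grade_probabilities Named simplex over poor/moderate/high for
#'   lesional specimens (default 38/26/15 out of 79).
#' @param grade_positive_probabilities Tibble with columns `marker`, `poor`,
#'   `moderate`, `high`.
#' @param stratify_lesional_by_grade Sample lesional positivity conditional
#'   on grade instead of at the group rate (default `FALSE`).
#' @param seed Integer seed.
#' @return An `ihc_config` list.
#' @export
ihc_config <- function(n_lesional = 79, n_perilesional = 79, n_normal = 39,
                       group_positive_probabilities = tibble(
                         marker = c("EZH2", "p57"),
                         lesional = c(0.7595, 0.4304),
                         perilesional = c(0.1519, 0.7975),
                         normal = c(0.1026, 0.9487)
                       ),
                       grade_probabilities = c(poor = 38, moderate = 26, high = 15) / 79,
                       grade_positive_probabilities = tibble(
                         marker = c("EZH2", "p57"),
                         poor = c(0.5526, 0.1683),
                         moderate = c(0.5385, 0.2059),
                         high = c(0.5333, 0.8079)
                       ),
                       stratify_lesional_by_grade = FALSE,
                       seed = 1L) {
  n_lesional <- check_count(n_lesional, "n_lesional")
  n_perilesional <- check_count(n_perilesional, "n_perilesional")
  n_normal <- check_count(n_normal, "n_normal")
  gpp <- as_tibble(group_positive_probabilities)
  for (col in c("lesional", "perilesional", "normal")) check_prob(gpp[[col]], col)
  grp <- as_tibble(grade_positive_probabilities)
  for (col in c("poor", "moderate", "high")) check_prob(grp[[col]], col)
  if (abs(sum(grade_probabilities) - 1) > 1e-9) {
    abort("`grade_probabilities` must sum to 1.")
  }
  structure(
    list(n_lesional = n_lesional, n_perilesional = n_perilesional,
         n_normal = n_normal,
         group_positive_probabilities = gpp,
         grade_probabilities = grade_probabilities[c("poor", "moderate", "high")],
         grade_positive_probabilities = grp,
         stratify_lesional_by_grade = stratify_lesional_by_grade,
         seed = as.integer(seed)),
    class = "ihc_config"
  )
}

#' Generate a synthetic immunohistochemistry cohort
#'
#' Samples per-specimen EZH2 and p57 positivity flags for the lesional,
#' perilesional and normal tissue groups; lesional specimens also carry a
#' differentiation grade. Aggregate with [expression_table()] or
#' [grade_stratified_rates()].
#'
#' @param config An [ihc_config()].
#' @return A long tibble with columns `specimen_id`, `group` (`"lesional"`,
#'   `"perilesional"`, `"normal"`), `grade` (lesional only), `marker`,
#'   `positive`.
#' @examples
#' spec <- generate_ihc_cohort(ihc_config(seed = 3))
#' expression_table(dplyr::filter(spec, marker == "EZH2"))
#' @export
generate_ihc_cohort <- function(config) {
  stopifnot(inherits(config, "ihc_config"))
  withr::with_seed(config$seed, {
    groups <- rep(c("lesional", "perilesional", "normal"),
                  c(config$n_lesional, config$n_perilesional, config$n_normal))
    n <- length(groups)
    grade <- rep(NA_character_, n)
    lesional <- groups == "lesional"
    grade[lesional] <- sample(names(config$grade_probabilities),
                              sum(lesional), TRUE, config$grade_probabilities)
    gpp <- config$group_positive_probabilities
    grp <- config$grade_positive_probabilities
    per_marker <- lapply(gpp$marker, function(mk) {
      pg <- gpp[gpp$marker == mk, ]
      p <- c(lesional = pg$lesional, perilesional = pg$perilesional,
             normal = pg$normal)[groups]
      if (config$stratify_lesional_by_grade) {
        gr <- grp[grp$marker == mk, ]
        p[lesional] <- c(poor = gr$poor, moderate = gr$moderate,
                         high = gr$high)[grade[lesional]]
      }
      tibble(
        specimen_id = seq_len(n),
        group = groups,
        grade = grade,
        marker = mk,
        positive = runif(n) < unname(p)
      )
    })
    dplyr::bind_rows(per_marker)
  })
}
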