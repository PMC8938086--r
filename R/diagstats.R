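#' Build a 2x2 diagnosis-versus-pathology contingency table
#'
#' Cross-tabulates binary diagnostic calls against the pathology gold
#' standard with malignant as the positive class: `tp` = called malignant and
#' truly malignant, `fp` = called malignant but benign, `fn`, `tn`
#' analogously.
#'
#' @param calls Character vector of `"benign"`/`"malignant"` calls.
#' @param truth Character vector of pathology labels, same length.
#' @return A `contingency_2x2` object (list with `tp`, `fp`, `fn`, `tn`).
#' @examples
#' build_contingency(c("malignant", "benign"), c("malignant", "malignant"))
#' @export
build_contingency <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    abort("`calls` and `truth` must be aligned one-to-one.")
  }
  lv <- c("benign", "malignant")
  if (!all(calls %in% lv) || !all(truth %in% lv)) {
    abort("Calls and truth must be \"benign\"/\"malignant\".")
  }
  contingency_2x2(
    tp = sum(calls == "malignant" & truth == "malignant"),
    fp = sum(calls == "malignant" & truth == "benign"),
    fn = sum(calls == "benign" & truth == "malignant"),
    tn = sum(calls == "benign" & truth == "benign")
  )
}

#' Construct a 2x2 contingency table from its cells
#'
#' @param tp,fp,fn,tn Non-negative counts (rows: call malignant/benign,
#'   columns: pathology malignant/benign).
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(cells) || any(cells < 0)) abort("Cell counts must be >= 0.")
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- as.matrix(x)
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
         dimnames = list(call = c("malignant", "benign"),
                         pathology = c("malignant", "benign")))
}

#' Diagnostic performance of a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and accuracy
#' `(tp+tn)/total`, returned both as raw fractions and as percentages
#' rounded half-up to 2 decimals (the convention of the reference tables).
#' A statistic whose denominator is zero is returned as `NA`.
#'
#' @param table A `contingency_2x2` (or list with `tp`, `fp`, `fn`, `tn`).
#' @return One-row tibble: `sensitivity`, `specificity`, `accuracy` (raw
#'   fractions) and `sensitivity_pct`, `specificity_pct`, `accuracy_pct`.
#' @examples
#' diagnostic_performance(contingency_2x2(24, 1, 3, 10))
#' @export
diagnostic_performance <- function(table) {
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  total <- tp + fp + fn + tn
  if (total == 0) abort("Empty contingency table.")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  tibble(
    sensitivity = sens, specificity = spec, accuracy = acc,
    sensitivity_pct = round_half_up(100 * sens),
    specificity_pct = round_half_up(100 * spec),
    accuracy_pct = round_half_up(100 * acc)
  )
}

#' Cohen's kappa for diagnosis-pathology agreement
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o = (tp + tn)/n` and chance agreement `p_e`
#' computed from the table margins. The interpretation band follows the
#' clinical convention used with these tables: `kappa >= 0.70` satisfactory,
#' `0.45 <= kappa < 0.70` good, `kappa < 0.45` poor.
#'
#' @param table A `contingency_2x2`.
#' @return A `kappa_test` list with `kappa`, `p_o`, `p_e` and `band`.
#'   Degenerate margins (`p_e = 1`) yield `kappa = NA`, band `"undefined"`.
#' @examples
#' cohen_kappa(contingency_2x2(24, 1, 3, 10))
#' @export
cohen_kappa <- function(table) {
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n <- tp + fp + fn + tn
  if (n == 0) abort("Empty contingency table.")
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    res <- list(kappa = NA_real_, p_o = p_o, p_e = p_e, band = "undefined")
  } else {
    k <- (p_o - p_e) / (1 - p_e)
    res <- list(kappa = k, p_o = p_o, p_e = p_e, band = kappa_band(k))
  }
  structure(res, class = "kappa_test")
}

kappa_band <- function(kappa) {
  if (kappa >= 0.70) "satisfactory" else if (kappa >= 0.45) "good" else "poor"
}

#' @export
print.kappa_test <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (p_o = %.4f, p_e = %.4f): %s agreement\n",
              x$kappa, x$p_o, x$p_e, x$band))
  invisible(x)
}

#' @export
tidy.kappa_test <- function(x, ...) {
  tibble(kappa = x$kappa, p_o = x$p_o, p_e = x$p_e, band = x$band)
}

#' @rdname tidy.contingency_2x2
#' @export
glance.contingency_2x2 <- function(x, ...) {
  perf <- diagnostic_performance(x)
  kap <- cohen_kappa(x)
  dplyr::bind_cols(perf, tibble(kappa = kap$kappa, kappa_band = kap$band))
}

#' Tidiers for 2x2 contingency tables
#'
#' `tidy()` returns the four cells in long form; `glance()` returns a
#' one-row summary with sensitivity, specificity, accuracy (raw and
#' percentage) and Cohen's kappa with its interpretation band.
#'
#' @param x A `contingency_2x2`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.contingency_2x2 <- function(x, ...) {
  tibble(
    call = c("malignant", "malignant", "benign", "benign"),
    pathology = c("malignant", "benign", "malignant", "benign"),
    n = c(x$tp, x$fp, x$fn, x$tn)
  )
}

#' Pearson chi-square test on a count grid
#'
#' Thin wrapper over [stats::chisq.test()] without continuity correction
#' (matching how association between categorical ultrasound/expression
#' features is tested here), returning a tidy row plus the expected counts.
#'
#' @param counts Numeric matrix (>= 2x2) of counts; rows/columns with zero
#'   margin are rejected.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return One-row tibble `statistic`, `df`, `p_value`, with expected counts
#'   in attribute `"expected"`.
#' @examples
#' chi_square_test(matrix(c(60, 12, 19, 67), 2))
#' @export
chi_square_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) abort("Need at least a 2x2 grid.")
  if (any(counts < 0)) abort("Counts must be >= 0.")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Zero-margin rows/columns are not allowed.")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  out <- tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value)
  )
  attr(out, "expected") <- ct$expected
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value by hypergeometric enumeration, via
#' [stats::fisher.test()]. Degenerate tables whose margins admit a single
#' configuration return p = 1.
#'
#' @param table A `contingency_2x2` or 2x2 count matrix.
#' @return The two-sided p-value.
#' @export
fisher_exact_test <- function(table) {
  m <- if (inherits(table, "contingency_2x2")) as.matrix(table) else as.matrix(table)
  if (!all(dim(m) == c(2, 2))) abort("Fisher test here expects a 2x2 table.")
  if (sum(m) == 0) return(1)
  stats::fisher.test(m)$p.value
}

#' Per-grade imaging-feature frequency table
#'
#' Tabulates, for each differentiation grade of the malignant lesions, the
#' count and percentage of every categorical imaging feature: shape,
#' boundary, internal echo, posterior echo, blood-flow band (0-1 vs 2-3),
#' elasticity band (1-3 vs 4-5), and CEUS enhancement pattern.
#'
#' @param lesions Lesion-level tibble as from [generate_cohort()]; every
#'   malignant lesion must carry a grade.
#' @return A tibble of class `feature_frequency_table` with columns `grade`,
#'   `feature`, `category`, `n`, `total`, `pct` (percentages rounded half-up
#'   to 2 decimals; `prop` carries the raw fraction).
#' @export
feature_frequency_table <- function(lesions) {
  lesions <- as_tibble(lesions)
  mal <- dplyr::filter(lesions, .data$pathology == "malignant")
  if (anyNA(mal$grade)) abort("Every malignant lesion must carry a grade.")
  mal <- mal |>
    dplyr::mutate(
      flow_band = ifelse(.data$flow_grade >= 2, "2-3", "0-1"),
      elasticity_band = ifelse(.data$elasticity_score >= 4, "4-5", "1-3")
    )
  feats <- c("shape", "boundary", "internal_echo", "posterior_echo",
             "flow_band", "elasticity_band", "ceus_pattern")
  out <- mal |>
    dplyr::select("grade", dplyr::all_of(feats)) |>
    tidyr::pivot_longer(dplyr::all_of(feats),
                        names_to = "feature", values_to = "category") |>
    dplyr::count(.data$grade, .data$feature, .data$category, name = "n") |>
    dplyr::group_by(.data$grade, .data$feature) |>
    dplyr::mutate(total = sum(.data$n), prop = .data$n / .data$total,
                  pct = round_half_up(100 * .data$prop)) |>
    dplyr::ungroup()
  class(out) <- c("feature_frequency_table", class(out))
  out
}
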