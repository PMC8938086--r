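#' Volumetric overlap error between two segmentation masks
#'
#' `voe(a, b) = 1 - |a intersect b| / |a union b|`, i.e. one minus the
#' Jaccard overlap: 0 for identical masks, 1 for disjoint non-empty masks.
#' Symmetric, bounded in \[0, 1\]. Two empty masks are treated as identical
#' (VOE 0), with a warning, since their union is empty.
#'
#' @param a,b Binary masks of identical shape.
#' @return A single number in \[0, 1\].
#' @examples
#' a <- matrix(c(1, 1, 1, 0), 2)
#' b <- matrix(c(1, 1, 0, 1), 2)
#' voe(a, b) # 1 - 2/4
#' @export
voe <- function(a, b) {
  check_mask(a, "a")
  check_mask(b, "b")
  check_same_shape(a, b)
  inter <- sum(a == 1 & b == 1)
  union <- sum(a == 1 | b == 1)
  if (union == 0) {
    warn("Both masks are empty; VOE defined as 0.")
    return(0)
  }
  1 - inter / union
}

#' Select the gold-standard annotation from a panel
#'
#' Operationalises "highest reliability" as the member with the minimal mean
#' VOE against all other members of the set; ties are broken by the lowest
#' annotator index. The result is always a member of the input set.
#'
#' @param set A list of >= 2 binary masks of identical shape (e.g. an
#'   `annotation_set` from [simulate_annotators()]).
#' @return The selected mask, with the winning index in attribute
#'   `"annotator"`.
#' @export
select_gold_standard <- function(set) {
  if (length(set) < 2) abort("Need at least 2 annotations.")
  for (m in set) check_mask(m)
  for (m in set[-1]) check_same_shape(set[[1]], m)
  k <- length(set)
  v <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      v[i, j] <- v[j, i] <- voe(set[[i]], set[[j]])
    }
  }
  mean_voe <- rowSums(v) / (k - 1)
  best <- which.min(mean_voe) # which.min takes the first minimum: tie-break
  structure(set[[best]], annotator = best, mean_voe = mean_voe[best])
}

#' Pixelwise confusion counts of a predicted mask against a gold standard
#'
#' @param pred,gold Binary masks of identical shape; `gold` defines the
#'   positive class.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn` summing to
#'   the number of pixels.
#' @examples
#' gold <- matrix(c(1, 1, 0, 0), 2)
#' pred <- matrix(c(1, 0, 1, 0), 2)
#' confusion_counts(pred, gold)
#' @export
confusion_counts <- function(pred, gold) {
  check_mask(pred, "pred")
  check_mask(gold, "gold")
  check_same_shape(pred, gold)
  structure(
    list(
      tp = sum(pred == 1 & gold == 1),
      fp = sum(pred == 1 & gold == 0),
      fn = sum(pred == 0 & gold == 1),
      tn = sum(pred == 0 & gold == 0)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts: TP", x$tp, "FP", x$fp, "FN", x$fn, "TN", x$tn, "\n")
  invisible(x)
}

#' Accuracy, precision and recall from confusion counts
#'
#' `accuracy = (TP + TN) / total`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`. A zero denominator makes the corresponding
#' statistic undefined and it is returned as `NA` (never silently as 0).
#'
#' @param counts A [confusion_counts()] object, or any list with elements
#'   `tp`, `fp`, `fn`, `tn`.
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total == 0) abort("Confusion counts sum to zero.")
  tibble(
    accuracy = (tp + tn) / total,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}

#' Average precision of a precision-recall curve
#'
#' Trapezoidal area under an explicit precision-recall point list:
#' `AP = 1/2 * sum_i (R_{i+1} - R_i) (P_{i+1} + P_i)`. The curve must have at
#' least two points with non-decreasing recall; precision and recall must lie
#' in \[0, 1\]. Threshold sweeping to produce the curve is the caller's job.
#'
#' @param recall,precision Numeric vectors of equal length (>= 2), or a
#'   two-column data frame given as `recall` with `precision` missing.
#' @return The area, in \[0, 1\].
#' @examples
#' average_precision(c(0, 1), c(1, 1)) # perfect classifier
#' average_precision(c(0, 0.5, 1), c(1, 0.8, 0.4))
#' @export
average_precision <- function(recall, precision = NULL) {
  if (is.data.frame(recall)) {
    precision <- recall$precision
    recall <- recall$recall
  }
  if (length(recall) < 2 || length(recall) != length(precision)) {
    abort("Need >= 2 (recall, precision) points of equal length.")
  }
  check_prob(recall, "recall")
  check_prob(precision, "precision")
  if (any(diff(recall) < 0)) abort("`recall` must be non-decreasing.")
  n <- length(recall)
  sum((recall[-1] - recall[-n]) * (precision[-1] + precision[-n])) / 2
}

#' Summarise segmentation quality of one mask against a gold standard
#'
#' Convenience wrapper combining [confusion_counts()],
#' [classification_metrics()] and [voe()] into a single tidy row, the unit
#' written to per-image metric tables.
#'
#' @inheritParams confusion_counts
#' @param id Optional image identifier carried into the output.
#' @return One-row tibble: `id`, `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `precision`, `recall`, `voe`.
#' @export
segmentation_summary <- function(pred, gold, id = NA_character_) {
  cc <- confusion_counts(pred, gold)
  dplyr::bind_cols(
    tibble(id = id, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn),
    classification_metrics(cc),
    tibble(voe = voe(pred, gold))
  )
}
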