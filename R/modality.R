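#' Benign/malignant call from Doppler blood-flow grade
#'
#' Intralesional colour-flow signal is graded 0-3; scant flow (grade 0-1)
#' calls the lesion benign, rich flow (grade 2-3) malignant.
#'
#' @param flow_grade Integer vector with values in 0..3.
#' @return Character vector of `"benign"` / `"malignant"`.
#' @examples
#' classify_doppler(0:3)
#' @export
classify_doppler <- function(flow_grade) {
  if (anyNA(flow_grade) || any(flow_grade < 0 | flow_grade > 3) ||
      any(flow_grade != as.integer(flow_grade))) {
    abort("`flow_grade` must be integers in 0..3.")
  }
  ifelse(flow_grade <= 1, "benign", "malignant")
}

#' Benign/malignant call from the elastography stiffness score
#'
#' Lesion stiffness is scored 1-5; soft lesions (score 1-3) call benign,
#' stiff lesions (score 4-5) malignant.
#'
#' @param score Integer vector with values in 1..5.
#' @return Character vector of `"benign"` / `"malignant"`.
#' @examples
#' classify_elastography(1:5)
#' @export
classify_elastography <- function(score) {
  if (anyNA(score) || any(score < 1 | score > 5) ||
      any(score != as.integer(score))) {
    abort("`score` must be integers in 1..5.")
  }
  ifelse(score <= 3, "benign", "malignant")
}

#' Benign/malignant call from contrast-enhanced ultrasound features
#'
#' A lesion is called benign (negative) only when neither malignant CEUS
#' feature is observed: no arterial-phase enhancement AND no portal/delayed
#' washout ("clearance"). Any observed enhancement or clearance calls the
#' lesion malignant. By default noncharacteristic findings are grouped with
#' "not observed" (the benign side); set `noncharacteristic_benign = FALSE`
#' to count them as positive findings instead.
#'
#' @param arterial Character vector: `"enhancement"`, `"non_enhancement"` or
#'   `"noncharacteristic"`.
#' @param washout Character vector: `"clearance"`, `"no_clearance"` or
#'   `"noncharacteristic"`.
#' @param noncharacteristic_benign Grouping of noncharacteristic findings
#'   (default `TRUE`, the benign side).
#' @return Character vector of `"benign"` / `"malignant"`.
#' @examples
#' classify_ceus("enhancement", "clearance")
#' classify_ceus("non_enhancement", "no_clearance")
#' @export
classify_ceus <- function(arterial, washout, noncharacteristic_benign = TRUE) {
  art_lv <- c("enhancement", "non_enhancement", "noncharacteristic")
  wash_lv <- c("clearance", "no_clearance", "noncharacteristic")
  if (!all(arterial %in% art_lv)) abort("Invalid `arterial` value.")
  if (!all(washout %in% wash_lv)) abort("Invalid `washout` value.")
  if (noncharacteristic_benign) {
    art_neg <- c("non_enhancement", "noncharacteristic")
    wash_neg <- c("no_clearance", "noncharacteristic")
  } else {
    art_neg <- "non_enhancement"
    wash_neg <- "no_clearance"
  }
  ifelse(arterial %in% art_neg & washout %in% wash_neg, "benign", "malignant")
}

#' Fuse single-modality calls into the multimodal verdict
#'
#' The multimodal rule is a logical AND on malignancy: the fused call is
#' malignant only when Doppler, elastography and CEUS all call malignant;
#' a single benign call makes the fused call benign.
#'
#' @param doppler,elastography,ceus Character vectors of
#'   `"benign"` / `"malignant"`, one element per lesion.
#' @return Character vector of fused calls.
#' @examples
#' fuse_multimodal("malignant", "malignant", "malignant")
#' fuse_multimodal("malignant", "malignant", "benign")
#' @export
fuse_multimodal <- function(doppler, elastography, ceus) {
  calls <- list(doppler = doppler, elastography = elastography, ceus = ceus)
  n <- unique(lengths(calls))
  if (length(n) != 1) abort("All three call vectors must have equal length.")
  for (nm in names(calls)) {
    if (!all(calls[[nm]] %in% c("benign", "malignant"))) {
      abort(sprintf("`%s` must contain only \"benign\"/\"malignant\".", nm))
    }
  }
  ifelse(doppler == "malignant" & elastography == "malignant" &
           ceus == "malignant", "malignant", "benign")
}

#' Apply all modality rules to a lesion findings table
#'
#' Adds one call column per modality plus the fused multimodal call to a
#' tibble of per-lesion findings, as produced by [generate_cohort()].
#'
#' @param findings Data frame with columns `flow_grade`, `elasticity_score`,
#'   `ceus_arterial`, `ceus_washout`.
#' @inheritParams classify_ceus
#' @return The input as a tibble with added columns `call_doppler`,
#'   `call_elastography`, `call_ceus`, `call_multimodal`.
#' @export
classify_lesions <- function(findings, noncharacteristic_benign = TRUE) {
  need <- c("flow_grade", "elasticity_score", "ceus_arterial", "ceus_washout")
  missing <- setdiff(need, names(findings))
  if (length(missing)) {
    abort(paste("`findings` is missing columns:", paste(missing, collapse = ", ")))
  }
  findings <- as_tibble(findings)
  findings |>
    dplyr::mutate(
      call_doppler = classify_doppler(.data$flow_grade),
      call_elastography = classify_elastography(.data$elasticity_score),
      call_ceus = classify_ceus(.data$ceus_arterial, .data$ceus_washout,
                                noncharacteristic_benign),
      call_multimodal = fuse_multimodal(.data$call_doppler,
                                        .data$call_elastography,
                                        .data$call_ceus)
    )
}
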