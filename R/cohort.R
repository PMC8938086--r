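#' Default per-stratum imaging-feature probabilities
#'
#' One row per lesion stratum (malignant grades `poor`, `moderate`, `high`,
#' plus `benign`) giving the probability of each malignant-leaning imaging
#' feature: irregular shape, unclear boundary, inhomogeneous internal echo,
#' unchanged-or-enhanced posterior echo, rich blood flow (Doppler grade 2-3),
#' high elasticity score (4-5), and the CEUS enhancement-pattern split
#' (fast-in-fast-out `p_fffo`, fast-in-no-out `p_ffno`, remainder
#' "other"/benign-looking). The malignant-grade rows are the published
#' per-grade frequencies for small hepatocellular carcinoma; benign-lesion
#' frequencies are unpublished, so the benign row is this package's
#' assumption of the complementary benign pattern and is fully overridable.
#'
#' @return A tibble with column `stratum` and seven probability columns.
#' @export
default_feature_probabilities <- function() {
  tibble(
    stratum = c("poor", "moderate", "high", "benign"),
    p_irregular = c(0.7959, 0.70, 0.3333, 0.20),
    p_unclear = c(0.7551, 0.70, 0.3333, 0.20),
    p_inhomogeneous = c(0.9388, 0.725, 0.3333, 0.20),
    p_posterior_unchanged = c(0.8980, 0.725, 0.50, 0.50),
    p_flow_high = c(0.9592, 0.90, 0.6667, 0.20),
    p_elastic_high = c(0.8980, 0.40, 0.50, 0.20),
    p_fffo = c(0.8367, 0.80, 0.5714, 0.05),
    p_ffno = c(0.10, 0.12, 0.20, 0.25)
  )
}

#' Configuration for the synthetic patient cohort
#'
#' Defaults emulate the reference study design: 100 patients randomised
#' evenly into four examination arms (Doppler, contrast, elastography,
#' multimodal); 26% of patients carry multiple (three) lesions so 152
#' lesions are expected; per-patient malignancy prevalence 0.79 (expected
#' 110 malignant vs 42 benign lesions); malignant lesions graded
#' poor/moderate/high with probabilities 49/110, 40/110, 21/110; lesion
#' diameters uniform on 0.8-3.0 cm; per-stratum imaging features from
#' [default_feature_probabilities()].
#'
#' @param n_patients Number of patients.
#' @param group_names Examination arms; patients are split as evenly as
#'   possible across them.
#' @param multiple_lesion_prob Probability a patient has multiple lesions.
#' @param lesions_if_multiple Lesion count for a multiple-lesion patient.
#' @param malignancy_prevalence Per-patient probability that all of the
#'   patient's lesions are malignant (pathology is a patient-level label).
#' @param grade_probabilities Named simplex over `poor`, `moderate`, `high`;
#'   sampled per lesion.
#' @param feature_probabilities Tibble as returned by
#'   [default_feature_probabilities()].
#' @param diameter_range_cm Range of lesion diameters (cm).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 100,
                          group_names = c("doppler", "contrast", "elastic", "multimodal"),
                          multiple_lesion_prob = 0.26,
                          lesions_if_multiple = 3,
                          malignancy_prevalence = 0.79,
                          grade_probabilities = c(poor = 49, moderate = 40, high = 21) / 110,
                          feature_probabilities = default_feature_probabilities(),
                          diameter_range_cm = c(0.8, 3.0),
                          seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  check_prob(multiple_lesion_prob, "multiple_lesion_prob")
  check_prob(malignancy_prevalence, "malignancy_prevalence")
  lesions_if_multiple <- check_count(lesions_if_multiple, "lesions_if_multiple", min = 2)
  if (abs(sum(grade_probabilities) - 1) > 1e-9) {
    abort("`grade_probabilities` must sum to 1.")
  }
  if (!all(c("poor", "moderate", "high") %in% names(grade_probabilities))) {
    abort("`grade_probabilities` must be named poor/moderate/high.")
  }
  fp <- as_tibble(feature_probabilities)
  need <- c("stratum", "p_irregular", "p_unclear", "p_inhomogeneous",
            "p_posterior_unchanged", "p_flow_high", "p_elastic_high",
            "p_fffo", "p_ffno")
  if (!all(need %in% names(fp)) ||
      !all(c("poor", "moderate", "high", "benign") %in% fp$stratum)) {
    abort("`feature_probabilities` must cover all strata and feature columns.")
  }
  for (col in setdiff(need, "stratum")) check_prob(fp[[col]], col)
  if (any(fp$p_fffo + fp$p_ffno > 1)) {
    abort("`p_fffo + p_ffno` must not exceed 1 in any stratum.")
  }
  structure(
    list(n_patients = n_patients, group_names = group_names,
         multiple_lesion_prob = multiple_lesion_prob,
         lesions_if_multiple = lesions_if_multiple,
         malignancy_prevalence = malignancy_prevalence,
         grade_probabilities = grade_probabilities[c("poor", "moderate", "high")],
         feature_probabilities = fp,
         diameter_range_cm = diameter_range_cm,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic multimodal-ultrasound cohort
#'
#' Samples patients, their examination arm, lesion counts, patient-level
#' pathology, per-lesion differentiation grade and per-lesion multimodal
#' imaging findings conditional on the stratum, per the configured
#' probabilities. Reproducible bit-for-bit under a fixed config and seed.
#'
#' @param config A [cohort_config()].
#' @return A lesion-level tibble with columns `patient_id`, `group`,
#'   `lesion_id`, `diameter_cm`, `pathology` (`"malignant"`/`"benign"`),
#'   `grade` (`"poor"`/`"moderate"`/`"high"`, `NA` for benign), `shape`,
#'   `boundary`, `internal_echo`, `posterior_echo`, `flow_grade`,
#'   `elasticity_score`, `ceus_pattern`, `ceus_arterial`, `ceus_washout`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 11))
#' dplyr::count(cohort, group)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    np <- config$n_patients
    groups <- sample(rep(config$group_names, length.out = np))
    n_lesions <- ifelse(runif(np) < config$multiple_lesion_prob,
                        config$lesions_if_multiple, 1L)
    pathology <- ifelse(runif(np) < config$malignancy_prevalence,
                        "malignant", "benign")
    lesions <- tibble(
      patient_id = rep(seq_len(np), n_lesions),
      group = rep(groups, n_lesions),
      pathology = rep(pathology, n_lesions)
    ) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(lesion_id = dplyr::row_number()) |>
      dplyr::ungroup()
    nl <- nrow(lesions)
    gp <- config$grade_probabilities
    grade <- sample(names(gp), nl, replace = TRUE, prob = gp)
    grade[lesions$pathology == "benign"] <- NA_character_
    stratum <- ifelse(is.na(grade), "benign", grade)
    fp <- config$feature_probabilities
    idx <- match(stratum, fp$stratum)
    draw <- function(p) runif(nl) < p[idx]
    irregular <- draw(fp$p_irregular)
    unclear <- draw(fp$p_unclear)
    inhomog <- draw(fp$p_inhomogeneous)
    post_unchanged <- draw(fp$p_posterior_unchanged)
    flow_high <- draw(fp$p_flow_high)
    elastic_high <- draw(fp$p_elastic_high)
    u <- runif(nl)
    pattern <- ifelse(u < fp$p_fffo[idx], "FFFO",
                      ifelse(u < fp$p_fffo[idx] + fp$p_ffno[idx], "FFNO", "other"))
    # ordinal scores consistent with the binary high/low feature draw
    flow_grade <- ifelse(flow_high, sample(2:3, nl, TRUE, c(0.6, 0.4)),
                         sample(0:1, nl, TRUE, c(0.4, 0.6)))
    elasticity <- ifelse(elastic_high, sample(4:5, nl, TRUE, c(0.6, 0.4)),
                         sample(1:3, nl, TRUE, c(0.2, 0.4, 0.4)))
    arterial <- ifelse(pattern %in% c("FFFO", "FFNO"), "enhancement",
                       sample(c("non_enhancement", "noncharacteristic"), nl, TRUE))
    washout <- ifelse(pattern == "FFFO", "clearance",
                      ifelse(pattern == "FFNO", "no_clearance",
                             sample(c("no_clearance", "noncharacteristic"), nl, TRUE)))
    lesions |>
      dplyr::mutate(
        diameter_cm = runif(nl, config$diameter_range_cm[1],
                            config$diameter_range_cm[2]),
        grade = grade,
        shape = ifelse(irregular, "irregular", "regular"),
        boundary = ifelse(unclear, "unclear", "clear"),
        internal_echo = ifelse(inhomog, "inhomogeneous", "homogeneous"),
        posterior_echo = ifelse(post_unchanged, "unchanged_or_enhanced", "attenuated"),
        flow_grade = as.integer(flow_grade),
        elasticity_score = as.integer(elasticity),
        ceus_pattern = pattern,
        ceus_arterial = arterial,
        ceus_washout = washout
      ) |>
      dplyr::select("patient_id", "group", "lesion_id", "diameter_cm",
                    "pathology", "grade", dplyr::everything())
  })
}
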