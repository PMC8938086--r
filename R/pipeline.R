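#' Configuration for an end-to-end synthetic run
#'
#' Bundles the sub-module configurations, stage toggles and a global seed.
#' Child seeds are derived deterministically from the global seed so each
#' stage can also be re-run on its own with the same result.
#'
#' @param seed Global integer seed.
#' @param stages Character vector of stages to run, a subset of
#'   `c("phantom", "cohort", "ihc", "replay")`.
#' @param phantom,annotators,cohort,ihc Optional sub-configs; defaults are
#'   built from the global seed.
#' @param output_dir Optional directory; when given, every tabular result is
#'   written there as CSV together with a provenance file recording the seed
#'   and a hash of the configuration.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("phantom", "cohort", "ihc", "replay"),
                            phantom = NULL, annotators = NULL,
                            cohort = NULL, ihc = NULL,
                            output_dir = NULL) {
  stages <- match.arg(stages, c("phantom", "cohort", "ihc", "replay"),
                      several.ok = TRUE)
  seed <- as.integer(seed)
  structure(
    list(
      seed = seed,
      stages = stages,
      phantom = phantom %||% phantom_config(seed = derive_seed(seed, 1)),
      annotators = annotators %||% annotator_config(seed = derive_seed(seed, 2)),
      cohort = cohort %||% cohort_config(seed = derive_seed(seed, 3)),
      ihc = ihc %||% ihc_config(seed = derive_seed(seed, 4)),
      output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts a YAML mapping with any of the [pipeline_config()] arguments at
#' the top level; sub-config blocks (`phantom`, `annotators`, `cohort`,
#' `ihc`) are passed to their respective constructors.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  spec <- yaml::read_yaml(path)
  args <- list(
    seed = spec$seed %||% 1L,
    stages = spec$stages %||% c("phantom", "cohort", "ihc", "replay"),
    output_dir = spec$output_dir
  )
  if (!is.null(spec$phantom)) args$phantom <- do.call(phantom_config, spec$phantom)
  if (!is.null(spec$annotators)) args$annotators <- do.call(annotator_config, spec$annotators)
  if (!is.null(spec$cohort)) args$cohort <- do.call(cohort_config, spec$cohort)
  if (!is.null(spec$ihc)) args$ihc <- do.call(ihc_config, spec$ihc)
  do.call(pipeline_config, args)
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order: phantom generation,
#' filtering and segmentation evaluation; cohort generation, per-modality
#' classification and per-arm diagnostic statistics; IHC cohort generation
#' and expression tables; and the reference-table replay. Identical config
#' and seed give identical results. With `output_dir` set, tabular results
#' are written as CSV alongside a `run_info.csv` provenance file.
#'
#' @param config A [pipeline_config()].
#' @return A named list of stage results:
#'   `segmentation` (per-annotator metric rows vs the selected gold
#'   standard), `cohort`, `diagnosis` (per-arm performance + kappa),
#'   `ihc_specimens`, `expression` (per-marker tables with rates and
#'   chi-square), and `replay` (see [replay_reference_tables()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list()

  if ("phantom" %in% config$stages) {
    ph <- generate_phantom(config$phantom)
    filtered <- adaptive_median_filter(ph$image)
    anns <- simulate_annotators(ph$mask, config$annotators)
    gold <- select_gold_standard(anns)
    out$segmentation <- purrr::imap_dfr(
      unclass(anns),
      function(m, i) segmentation_summary(m, gold, id = paste0("annotator_", i))
    )
    out$filtered_mae <- mean(abs(filtered - ph$clean))
  }

  if ("cohort" %in% config$stages) {
    cohort <- classify_lesions(generate_cohort(config$cohort))
    out$cohort <- cohort
    call_col <- c(doppler = "call_doppler", contrast = "call_ceus",
                  elastic = "call_elastography", multimodal = "call_multimodal")
    arms <- intersect(names(call_col), unique(cohort$group))
    out$diagnosis <- purrr::map_dfr(arms, function(arm) {
      sub <- dplyr::filter(cohort, .data$group == arm)
      tab <- build_contingency(sub[[call_col[[arm]]]], sub$pathology)
      dplyr::bind_cols(tibble(group = arm), glance(tab))
    })
    out$feature_frequencies <- feature_frequency_table(cohort)
  }

  if ("ihc" %in% config$stages) {
    spec <- generate_ihc_cohort(config$ihc)
    out$ihc_specimens <- spec
    out$expression <- spec |>
      dplyr::group_by(.data$marker) |>
      dplyr::group_modify(function(d, key) {
        tab <- expression_table(d)
        chisq <- compare_expression(tab)
        tab |>
          dplyr::mutate(
            rate_pct = round_half_up(100 * .data$positive /
                                       (.data$positive + .data$negative)),
            chisq_statistic = chisq$statistic,
            chisq_p_value = chisq$p_value
          )
      }) |>
      dplyr::ungroup()
  }

  if ("replay" %in% config$stages) {
    out$replay <- replay_reference_tables()
  }

  if (!is.null(config$output_dir)) {
    write_pipeline_outputs(out, config)
  }
  out
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  tab_names <- c("segmentation", "cohort", "diagnosis", "feature_frequencies",
                 "ihc_specimens", "expression")
  for (nm in intersect(tab_names, names(out))) {
    utils::write.csv(out[[nm]], file.path(config$output_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(out$replay)) {
    utils::write.csv(out$replay$diagnosis,
                     file.path(config$output_dir, "replay_diagnosis.csv"),
                     row.names = FALSE)
    utils::write.csv(out$replay$expression,
                     file.path(config$output_dir, "replay_expression.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(
    tibble(seed = config$seed,
           config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
           stages = paste(config$stages, collapse = ";")),
    file.path(config$output_dir, "run_info.csv"), row.names = FALSE
  )
  invisible(NULL)
}
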