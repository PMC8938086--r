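test_that("replay reproduces every arithmetically consistent statistic", {
  rep <- replay_reference_tables()
  d <- rep$diagnosis
  get <- function(grp, stat) d$computed[d$group == grp & d$statistic == stat]
  expect_equal(get("contrast", "sensitivity_pct"), 58.06)
  expect_equal(get("contrast", "accuracy_pct"), 60.00)
  expect_equal(get("elastic", "sensitivity_pct"), 61.54)
  expect_equal(get("elastic", "specificity_pct"), 70.00)
  expect_equal(get("elastic", "accuracy_pct"), 63.89)
  expect_equal(get("doppler", "specificity_pct"), 66.67)
  expect_equal(get("doppler", "accuracy_pct"), 63.16)
  expect_equal(get("multimodal", "specificity_pct"), 90.91)
  expect_equal(get("multimodal", "accuracy_pct"), 89.47)
})

test_that("replay flags the known-inconsistent printed values", {
  rep <- replay_reference_tables()
  d <- rep$diagnosis
  flag <- function(grp, stat) d$discrepancy[d$group == grp & d$statistic == stat]
  expect_true(flag("doppler", "sensitivity_pct"))    # 16/26 vs printed 57.69
  expect_true(flag("multimodal", "sensitivity_pct")) # 24/27 vs printed 88.87
  expect_true(all(d$discrepancy[d$statistic == "kappa"]))
  # and only those: the ten cell-consistent statistics (including contrast
  # specificity 6/9) carry no flag
  expect_equal(sum(!d$discrepancy), 10)
})

test_that("expression replay reproduces consistent rates and flags the rest", {
  rep <- replay_reference_tables()
  e <- rep$expression
  rate <- function(mk, grp) e$computed_rate_pct[e$marker == mk & e$group == grp]
  expect_equal(rate("EZH2", "lesional"), 75.95)
  expect_equal(rate("EZH2", "perilesional"), 15.19)
  expect_equal(rate("EZH2", "normal"), 10.26)
  expect_equal(rate("p57", "perilesional"), 79.75)
  expect_equal(rate("p57", "normal"), 94.87)
  expect_true(e$discrepancy[e$marker == "p57" & e$group == "lesional"])
  expect_equal(sum(e$discrepancy), 1)
})

test_that("pipeline runs end to end, deterministically, with stage toggles", {
  cfg <- pipeline_config(seed = 5,
                         phantom = phantom_config(height = 32, width = 32,
                                                  seed = 42),
                         cohort = cohort_config(n_patients = 40, seed = 43))
  res <- run_pipeline(cfg)
  expect_named(res, c("segmentation", "filtered_mae", "cohort", "diagnosis",
                      "feature_frequencies", "ihc_specimens", "expression",
                      "replay"), ignore.order = TRUE)
  expect_equal(nrow(res$diagnosis), 4)
  expect_equal(dplyr::n_distinct(res$expression$group), 3)
  res2 <- run_pipeline(cfg)
  expect_identical(res$diagnosis, res2$diagnosis)
  expect_identical(res$cohort, res2$cohort)

  none <- run_pipeline(pipeline_config(seed = 1, stages = "replay"))
  expect_named(none, "replay")
})

test_that("pipeline CSV outputs are byte-identical across same-seed runs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  base <- list(seed = 5, cohort = cohort_config(n_patients = 20, seed = 12),
               phantom = phantom_config(height = 24, width = 24, seed = 13))
  run_pipeline(do.call(pipeline_config, c(base, list(output_dir = d1))))
  run_pipeline(do.call(pipeline_config, c(base, list(output_dir = d2))))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_true("run_info.csv" %in% list.files(d1))
})

test_that("config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 9",
    "stages: [cohort, replay]",
    "cohort:",
    "  n_patients: 16",
    "  seed: 3"
  ), path)
  cfg <- read_pipeline_config(path)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$cohort$n_patients, 16)
  res <- run_pipeline(cfg)
  expect_true(all(c("cohort", "replay") %in% names(res)))
  expect_false("ihc_specimens" %in% names(res))
})

test_that("image and mask round-trip through PNG and TIFF", {
  img <- round(matrix(seq(0, 255, length.out = 64), 8, 8))
  for (ext in c(".png", ".tif")) {
    path <- withr::local_tempfile(fileext = ext)
    write_image(img, path)
    expect_equal(read_image(path), img, ignore_attr = TRUE)
  }
  mask <- matrix(rbinom(64, 1, 0.5), 8, 8)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(mask, path)
  expect_equal(read_mask(path), mask, ignore_attr = TRUE)
})
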