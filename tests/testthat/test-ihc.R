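test_that("product rule is strict at 3 and monotone in both scores", {
  expect_true(score_specimen(2, 2)$positive)   # product 4
  expect_false(score_specimen(1, 3)$positive)  # product exactly 3
  expect_false(score_specimen(0, 4)$positive)
  expect_false(score_specimen(3, 0)$positive)
  expect_true(score_specimen(3, 4)$positive)
  # monotonicity over the full score grid
  grid <- expand.grid(i = 0:3, p = 0:4)
  pos <- score_specimen(grid$i, grid$p)$positive
  for (r in seq_len(nrow(grid))) {
    if (!pos[r]) next
    higher <- grid$i >= grid$i[r] & grid$p >= grid$p[r]
    expect_true(all(pos[higher]))
  }
  expect_error(score_specimen(4, 1), "intensity_score")
  expect_error(score_specimen(1, 5), "percent_score")
})

test_that("positive rates reproduce the reference arithmetic", {
  ezh2 <- tibble::tibble(group = c("lesional", "perilesional", "normal"),
                         negative = c(19, 67, 35), positive = c(60, 12, 4))
  expect_equal(as.numeric(positive_rate(ezh2, "lesional")), 75.95)
  expect_equal(as.numeric(positive_rate(ezh2, "perilesional")), 15.19)
  expect_equal(as.numeric(positive_rate(ezh2, "normal")), 10.26)
  p57 <- tibble::tibble(group = c("perilesional", "normal"),
                        negative = c(16, 2), positive = c(63, 37))
  expect_equal(as.numeric(positive_rate(p57, "normal")), 94.87)
  all_pos <- tibble::tibble(group = "g", negative = 0, positive = 12)
  expect_equal(as.numeric(positive_rate(all_pos, "g")), 100)
  # rate times row sum recovers the positive count exactly before rounding
  expect_equal(attr(positive_rate(ezh2, "lesional"), "prop") * 79, 60)
  expect_error(positive_rate(ezh2, "missing"), "not found")
})

test_that("default IHC cohort has the reference group sizes", {
  spec <- generate_ihc_cohort(ihc_config(seed = 7))
  tab <- expression_table(dplyr::filter(spec, marker == "EZH2"))
  expect_equal(sort(tab$negative + tab$positive), sort(c(79, 79, 39)))
  expect_equal(ncol(tab), 3) # group, negative, positive
  expect_identical(generate_ihc_cohort(ihc_config(seed = 7)), spec)
  # lesional specimens carry grades, others do not
  expect_true(all(!is.na(spec$grade[spec$group == "lesional"])))
  expect_true(all(is.na(spec$grade[spec$group != "lesional"])))
})

test_that("boundary positivity probabilities behave as configured", {
  cfg <- ihc_config(
    group_positive_probabilities = tibble::tibble(
      marker = c("EZH2", "p57"), lesional = c(1, 1),
      perilesional = c(1, 1), normal = c(1, 1)),
    seed = 4)
  spec <- generate_ihc_cohort(cfg)
  expect_true(all(spec$positive))
})

test_that("scaled-up cohort recovers configured positivity within tolerance", {
  cfg <- ihc_config(n_lesional = 7900, n_perilesional = 7900, n_normal = 3900,
                    seed = 21)
  spec <- generate_ihc_cohort(cfg)
  ezh2 <- expression_table(dplyr::filter(spec, marker == "EZH2"))
  rate <- attr(positive_rate(ezh2, "lesional"), "prop")
  expect_lt(abs(rate - 0.7595), 0.015)
})

test_that("grade-stratified sampling recovers per-grade probabilities", {
  cfg <- ihc_config(n_lesional = 15000, n_perilesional = 1, n_normal = 1,
                    grade_probabilities = c(poor = 1, moderate = 1, high = 1) / 3,
                    stratify_lesional_by_grade = TRUE, seed = 9)
  spec <- generate_ihc_cohort(cfg) |>
    dplyr::filter(group == "lesional")
  rates <- grade_stratified_rates(spec)
  p57 <- dplyr::filter(rates, marker == "p57")
  configured <- c(poor = 0.1683, moderate = 0.2059, high = 0.8079)
  for (g in names(configured)) {
    expect_lt(abs(p57$prop[p57$grade == g] - configured[[g]]), 0.02)
  }
  # permutation invariance
  shuffled <- spec[sample(nrow(spec)), ]
  expect_equal(dplyr::arrange(grade_stratified_rates(shuffled), marker, grade),
               dplyr::arrange(rates, marker, grade))
  # single grade present gives a one-row table per marker
  one <- grade_stratified_rates(dplyr::filter(spec, grade == "poor",
                                              marker == "p57"))
  expect_equal(nrow(one), 1)
  expect_error(grade_stratified_rates(dplyr::mutate(spec, grade = NA)), "grade")
})

test_that("expression comparison delegates to the Pearson chi-square", {
  same <- tibble::tibble(group = c("a", "b"), negative = c(10, 10),
                         positive = c(5, 5))
  expect_equal(compare_expression(same)$statistic, 0)
  tab2 <- reference_expression_tables() |>
    dplyr::filter(marker == "EZH2") |>
    dplyr::select(group, negative, positive)
  res <- compare_expression(tab2)
  m <- as.matrix(tab2[, c("negative", "positive")])
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(res$statistic, sum((m - expected)^2 / expected), tolerance = 1e-10)
  expect_lt(res$p_value, 0.001)
})
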