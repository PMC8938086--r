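test_that("contingency building tallies calls against pathology", {
  calls <- c("malignant", "malignant", "benign", "benign")
  truth <- c("malignant", "benign", "malignant", "benign")
  tab <- build_contingency(calls, truth)
  expect_equal(unclass(tab), list(tp = 1, fp = 1, fn = 1, tn = 1))

  perfect <- build_contingency(truth, truth)
  expect_equal(perfect$fp + perfect$fn, 0)
  expect_error(build_contingency(calls, truth[1:3]), "one-to-one")

  set.seed(30)
  c2 <- sample(c("benign", "malignant"), 200, TRUE)
  t2 <- sample(c("benign", "malignant"), 200, TRUE)
  tab2 <- build_contingency(c2, t2)
  # recount oracle
  expect_equal(tab2$tp, sum(c2 == "malignant" & t2 == "malignant"))
  expect_equal(tab2$tn, sum(c2 == "benign" & t2 == "benign"))
  expect_equal(tab2$tp + tab2$fp + tab2$fn + tab2$tn, 200)
})

test_that("diagnostic performance reproduces the reference arithmetic", {
  multi <- diagnostic_performance(contingency_2x2(24, 1, 3, 10))
  expect_equal(multi$specificity_pct, 90.91)
  expect_equal(multi$accuracy_pct, 89.47)
  elastic <- diagnostic_performance(contingency_2x2(16, 3, 10, 7))
  expect_equal(elastic$sensitivity_pct, 61.54)
  expect_equal(elastic$specificity_pct, 70.00)
  expect_equal(elastic$accuracy_pct, 63.89)
  perfect <- diagnostic_performance(contingency_2x2(5, 0, 0, 5))
  expect_equal(c(perfect$sensitivity_pct, perfect$specificity_pct,
                 perfect$accuracy_pct), c(100, 100, 100))
  und <- diagnostic_performance(contingency_2x2(0, 2, 0, 3))
  expect_true(is.na(und$sensitivity))
})

test_that("accuracy times total equals tp + tn exactly before rounding", {
  set.seed(8)
  for (i in 1:25) {
    cells <- sample(0:30, 4, replace = TRUE)
    if (sum(cells) == 0) next
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    perf <- diagnostic_performance(tab)
    expect_equal(perf$accuracy * sum(cells), cells[1] + cells[4])
  }
})

test_that("Cohen's kappa matches direct p_o/p_e computation and its bands", {
  perfect <- cohen_kappa(contingency_2x2(7, 0, 0, 7))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$band, "satisfactory")

  chance <- cohen_kappa(contingency_2x2(25, 25, 25, 25))
  expect_equal(chance$kappa, 0)
  expect_equal(chance$band, "poor")

  # hand computation for the multimodal reference cells
  k <- cohen_kappa(contingency_2x2(24, 1, 3, 10))
  p_o <- 34 / 38
  p_e <- (25 * 27 + 13 * 11) / 38^2
  expect_equal(k$kappa, (p_o - p_e) / (1 - p_e))
  expect_equal(k$band, "satisfactory")

  mid <- cohen_kappa(contingency_2x2(20, 5, 6, 15))
  expect_true(mid$band %in% c("poor", "good", "satisfactory"))
  degen <- cohen_kappa(contingency_2x2(5, 0, 0, 0))
  expect_true(is.na(degen$kappa))
  expect_equal(degen$band, "undefined")
})

test_that("kappa agrees with an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(12)
  for (i in 1:20) {
    cells <- sample(1:40, 4, replace = TRUE)
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    ours <- cohen_kappa(tab)$kappa
    theirs <- e1071::classAgreement(as.matrix(tab))$kappa
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("kappa is invariant under simultaneous row/column transposition", {
  set.seed(19)
  for (i in 1:10) {
    cells <- sample(1:30, 4, replace = TRUE)
    a <- cohen_kappa(contingency_2x2(cells[1], cells[2], cells[3], cells[4]))$kappa
    # swap positive/negative labels on both axes: tp<->tn, fp<->fn
    b <- cohen_kappa(contingency_2x2(cells[4], cells[3], cells[2], cells[1]))$kappa
    expect_equal(a, b)
  }
})

test_that("chi-square agrees with the sum over (O-E)^2/E", {
  even <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  set.seed(6)
  for (i in 1:10) {
    m <- matrix(sample(5:40, 6, replace = TRUE), 2, 3)
    res <- chi_square_test(m)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(res$statistic, sum((m - expected)^2 / expected),
                 tolerance = 1e-10)
    # doubling every count doubles the Pearson statistic
    expect_equal(chi_square_test(2 * m)$statistic, 2 * res$statistic,
                 tolerance = 1e-10)
  }
  expect_error(chi_square_test(matrix(c(0, 0, 5, 6), 2, byrow = TRUE)), "margin")
})

test_that("Fisher's exact test matches full enumeration for small tables", {
  # margins (5,5)x(5,5): hypergeometric over tables with tp in 0..5
  p_table <- function(tp) stats::dhyper(tp, 5, 5, 5)
  probs <- vapply(0:5, p_table, numeric(1))
  observed <- p_table(5)
  p_enum <- sum(probs[probs <= observed + 1e-12])
  expect_equal(fisher_exact_test(contingency_2x2(5, 0, 0, 5)), p_enum,
               tolerance = 1e-12)
  expect_equal(fisher_exact_test(contingency_2x2(0, 0, 0, 8)), 1)
  # symmetry: swapping the rows leaves p unchanged
  expect_equal(fisher_exact_test(contingency_2x2(3, 7, 2, 9)),
               fisher_exact_test(contingency_2x2(2, 9, 3, 7)),
               tolerance = 1e-12)
})

test_that("feature frequency table closes to 100% per binary attribute", {
  cohort <- generate_cohort(cohort_config(n_patients = 200, seed = 44))
  freq <- feature_frequency_table(cohort)
  sums <- freq |>
    dplyr::group_by(grade, feature) |>
    dplyr::summarise(p = sum(prop), .groups = "drop")
  expect_true(all(abs(sums$p - 1) < 1e-12))
  # single-lesion input: its categories at 100%
  one <- feature_frequency_table(cohort[which(cohort$pathology == "malignant")[1], ])
  expect_true(all(one$pct == 100))
  # ungraded malignant lesion rejected
  broken <- cohort
  broken$grade[broken$pathology == "malignant"][1] <- NA
  expect_error(feature_frequency_table(broken), "grade")
})

test_that("contingency tidiers expose cells and summary statistics", {
  tab <- contingency_2x2(24, 1, 3, 10)
  td <- tidy(tab)
  expect_equal(sum(td$n), 38)
  gl <- glance(tab)
  expect_equal(gl$accuracy_pct, 89.47)
  expect_true(gl$kappa_band %in% c("poor", "good", "satisfactory"))
})
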