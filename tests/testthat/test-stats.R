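test_that("the closed-form chi-square matches printed pre/post statistics", {
  # menorrhagia 137/408 pre vs 17/408 post
  expect_equal(pearson_chi2(two_by_two(137, 271, 17, 391))$statistic,
               115.259, tolerance = 5e-4)
  # dysmenorrhea 135/408 vs 64/408
  expect_equal(pearson_chi2(two_by_two(135, 273, 64, 344))$statistic,
               33.502, tolerance = 5e-4)
  # identical rows -> exactly zero
  expect_equal(pearson_chi2(two_by_two(30, 70, 30, 70))$statistic, 0)
  # zero marginal is undefined
  expect_error(pearson_chi2(two_by_two(0, 10, 0, 20)),
               class = "perisym_data_error")
})

test_that("chi-square equals the generic observed-expected form and chisq.test", {
  set.seed(101)
  for (i in 1:200) {
    cells <- rpois(4, lambda = sample(3:40, 1)) + 1
    tab <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    m <- matrix(cells, 2, 2, byrow = TRUE)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    generic <- sum((m - E)^2 / E)
    expect_equal(pearson_chi2(tab)$statistic, generic, tolerance = 1e-9)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(pearson_chi2(tab)$statistic, unname(ref$statistic))
    expect_equal(pearson_chi2(tab)$p, unname(ref$p.value))
    # invariant to transposition
    tt <- two_by_two(cells[1], cells[3], cells[2], cells[4])
    expect_equal(pearson_chi2(tt)$statistic, pearson_chi2(tab)$statistic)
  }
})

test_that("odds ratios reproduce the printed risk-screen values", {
  # age > 40: 58/151 exposed vs 77/111 unexposed
  or_age <- odds_ratio(two_by_two(58, 151, 77, 111))
  expect_equal(round(or_age$or, 2), 0.55)
  expect_equal(round(or_age$ci_low, 2), 0.36)
  expect_equal(round(or_age$ci_high, 2), 0.84)
  # BMI >= 24: 51/64 vs 84/198
  or_bmi <- odds_ratio(two_by_two(51, 64, 84, 198))
  expect_equal(round(or_bmi$or, 2), 1.88)
  expect_equal(round(or_bmi$ci_low, 2), 1.20)
  expect_equal(round(or_bmi$ci_high, 2), 2.94)
  # null association when ad = bc
  expect_equal(odds_ratio(two_by_two(20, 40, 10, 20))$or, 1)
  # swapping exposure rows gives the reciprocal
  a <- odds_ratio(two_by_two(12, 30, 7, 44))
  b <- odds_ratio(two_by_two(7, 44, 12, 30))
  expect_equal(a$or, 1 / b$or)
  expect_equal(a$ci_low, 1 / b$ci_high)
  # zero cell errors with a pointer to the correction
  expect_error(odds_ratio(two_by_two(0, 10, 5, 5)), "Haldane",
               class = "perisym_data_error")
})

test_that("continuous comparisons match closed forms and detect planted shifts", {
  x <- c(5.1, 4.8, 6.0, 5.5, 5.2)
  y <- c(4.2, 4.9, 4.4, 5.0, 4.1)
  got <- compare_continuous(x, y, method = "t")
  # Welch statistic computed from the definition
  tstat <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(unname(got$statistic), tstat)

  # elementwise-equal paired samples: statistic 0-ish, p = 1 convention
  same <- compare_continuous(x, x + 0, method = "wilcoxon", paired = TRUE)
  expect_equal(unname(same$p.value), 1)

  withr::with_seed(5, {
    a <- rnorm(200)
    b <- rnorm(200, mean = 1)
  })
  expect_lt(compare_continuous(a, b, method = "t")$p.value, 1e-3)
  expect_error(compare_continuous(rep(1, 5), rep(2, 5)),
               class = "perisym_data_error")
})

test_that("the Bonferroni cutoff is alpha over k", {
  expect_equal(bonferroni_cutoff(0.05, 5), 0.01)
  expect_equal(bonferroni_cutoff(0.05, 1), 0.05)
  expect_equal(bonferroni_cutoff(0.10, 4), 0.025)
  expect_error(bonferroni_cutoff(0.05, 0), class = "perisym_config_error")
})

test_that("the preoperative risk screen reproduces the printed age-group p-value", {
  # rebuild the screen input from printed counts: 135 dysmenorrhea cases,
  # 262 controls; 58 cases and 151 controls aged > 40
  ehr <- data.frame(
    patient_key = sprintf("P%03d", 1:397),
    age = c(rep(45, 58), rep(35, 77), rep(45, 151), rep(35, 111)),
    stringsAsFactors = FALSE
  )
  outcome <- c(rep(TRUE, 135), rep(FALSE, 262))
  res <- risk_factor_screen(ehr, outcome,
                            factors = list(age = list(var = "age", cut = 40,
                                                      exposure = ">")))
  expect_equal(round(res$p, 3), 0.006)
  expect_equal(round(res$or, 2), 0.55)
  expect_equal(res$cutoff, 0.05)

  # k factors -> k rows and cutoff alpha/k; null factor covers OR = 1
  withr::with_seed(23, {
    n <- 5000
    ehr2 <- data.frame(patient_key = seq_len(n),
                       age = sample(30:50, n, replace = TRUE),
                       bmi = rnorm(n, 23, 3))
    out2 <- runif(n) < 0.3  # independent of both factors
  })
  res2 <- risk_factor_screen(ehr2, out2,
                             factors = default_risk_factors()[c("age", "bmi")])
  expect_equal(nrow(res2), 2)
  expect_equal(unique(res2$cutoff), 0.025)
  expect_true(all(res2$ci_low < 1 & res2$ci_high > 1))

  # single-level factor is skipped with a warning
  ehr3 <- data.frame(patient_key = 1:10, age = rep(50, 10))
  expect_warning(
    res3 <- risk_factor_screen(ehr3, rep(c(TRUE, FALSE), 5),
                               factors = list(age = list(var = "age",
                                                         cut = 40,
                                                         exposure = ">"))),
    "single level")
  expect_null(res3)
})

test_that("the postoperative GEE screen flags a planted risk factor", {
  withr::with_seed(31, {
    n <- 600
    expo <- rbinom(n, 1, 0.5)
    keys <- sprintf("P%04d", seq_len(n))
    win <- rep(c("M1", "M2", "M3", "M4_6"), times = n)
    id <- rep(keys, each = 4)
    y <- rbinom(length(win), 1, plogis(-2 + 1.2 * expo[match(id, keys)]))
  })
  pm <- data.frame(patient_key = id, concept_id = "menorrhagia",
                   window = win, present = as.logical(y),
                   stringsAsFactors = FALSE)
  ehr <- data.frame(patient_key = keys, age = ifelse(expo == 1, 45, 35),
                    stringsAsFactors = FALSE)
  res <- postop_gee_screen(pm, ehr,
                           factors = list(age = list(var = "age", cut = 40,
                                                     exposure = ">")))
  expect_equal(nrow(res), 1)
  expect_lt(abs(res$estimate - 1.2), 3 * res$se)
  expect_true(res$significant)
})
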