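test_that("cohort generation respects size, bounds and the planted age distribution", {
  cfg <- cohort_config(n_patients = 0)
  expect_equal(nrow(generate_cohort(cfg)), 0)

  cfg <- cohort_config(n_patients = 10000, seed = 5)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 10000)
  expect_false(anyDuplicated(coh$patient_key) > 0)
  expect_true(all(as.Date(coh$surgery_date) >= cfg$surgery_date_range[1]))
  expect_true(all(as.Date(coh$surgery_date) <= cfg$surgery_date_range[2]))
  expect_true(all(coh$age >= 18 & coh$age <= 70))
  # planted mean age 39.94 (SD 6.81): sample mean within 3 standard errors
  expect_lt(abs(mean(coh$age) - 39.94), 3 * 6.81 / sqrt(10000))
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- cohort_config(n_patients = 15, seed = 99, noise_rate = 0.3,
                       ocr_noise_rate = 0.02)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a, b)
  ca <- generate_chat(a, cfg); cb <- generate_chat(b, cfg)
  expect_identical(ca, cb)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = -1), class = "perisym_config_error")
  expect_error(cohort_config(negation_rate = 1.2), class = "perisym_config_error")
  expect_error(cohort_config(prevalence = list(dysmenorrhea = c(BAD = 0.2))),
               class = "perisym_config_error")
  cfg <- cohort_config(n_patients = 2)
  cfg$prevalence <- list(not_a_concept = c(PREOP = 0.5))
  expect_error(generate_chat(generate_cohort(cohort_config(n_patients = 2)), cfg),
               class = "perisym_config_error")
})

test_that("zero prevalence with zero rates yields no gold labels", {
  prev <- list(dysmenorrhea = c(PREOP = 0, M1 = 0, M2 = 0, M3 = 0, M4_6 = 0))
  st <- make_study(n = 5, noise_rate = 0, negation_rate = 0,
                   prevalence = prev)
  expect_equal(nrow(st$gold), 0)
  # only the identity scaffold remains
  expect_true(all(grepl("住院号", st$corpus$text)))
})

test_that("planted prevalence converges to the configured probability", {
  prev <- list(dysmenorrhea = c(PREOP = 0.331, M1 = 0, M2 = 0, M3 = 0,
                                M4_6 = 0))
  st <- make_study(n = 5000, seed = 7, noise_rate = 0, negation_rate = 0,
                   prevalence = prev)
  hit <- unique(st$gold$patient_key[st$gold$polarity == "affirmed" &
                                      st$gold$window == "PREOP"])
  frac <- length(hit) / 5000
  expect_lt(abs(frac - 0.331), 3 * sqrt(0.331 * 0.669 / 5000))
})

test_that("every gold span indexes into its message text", {
  st <- make_study(n = 40, seed = 3, noise_rate = 0.25, negation_rate = 0.2)
  idx <- match(st$gold$message_id, st$corpus$message_id)
  expect_false(anyNA(idx))
  len <- nchar(st$corpus$text[idx])
  expect_true(all(st$gold$start >= 0))
  expect_true(all(st$gold$end <= len))
  # and the span really contains the recorded term
  got <- substring(st$corpus$text[idx], st$gold$start + 1, st$gold$end)
  expect_identical(got, st$gold$term)
})

test_that("OCR corruption preserves length and hits the configured rate", {
  expect_identical(inject_ocr_noise("痛经没有复发", 0), "痛经没有复发")
  everything <- inject_ocr_noise("痛经", 1, seed = 4)
  expect_equal(nchar(everything), 2)
  orig <- strsplit("痛经", "")[[1]]
  expect_true(all(strsplit(everything, "")[[1]] != orig))

  txt <- paste(rep("月经量多没有血块头晕乏力", 10000), collapse = "")
  out <- inject_ocr_noise(txt, 0.05, seed = 9)
  n <- nchar(txt)
  expect_equal(nchar(out), n)
  frac <- mean(strsplit(txt, "")[[1]] != strsplit(out, "")[[1]])
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("empty cohort produces an empty corpus and gold set", {
  cfg <- cohort_config(n_patients = 0)
  out <- generate_chat(generate_cohort(cfg), cfg)
  expect_equal(nrow(out$corpus), 0)
  expect_equal(nrow(out$gold), 0)
})
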