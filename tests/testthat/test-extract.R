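lex <- shipped_lexicon()

test_that("mention detection is longest-first, non-overlapping per concept", {
  mm <- detect_mentions("月经量多还有血块", lex)
  expect_setequal(mm$concept_id, c("menorrhagia", "menstrual_blood_clots"))
  expect_equal(mm$start[mm$concept_id == "menorrhagia"], 0)
  expect_equal(mm$end[mm$concept_id == "menorrhagia"], 4)  # not 经量多 at 1

  expect_equal(nrow(detect_mentions("今天天气不错", lex)), 0)

  # two occurrences of the same concept are both reported
  mm2 <- detect_mentions("痛经，还是痛经", lex)
  expect_equal(sum(mm2$concept_id == "dysmenorrhea"), 2)
})

test_that("polarity follows the bounded pre-term negation window", {
  expect_identical(classify_polarity("没有痛经", 2, lex), "negated")
  # cue after the term does not negate
  expect_identical(classify_polarity("痛经好了没有来月经", 0, lex), "affirmed")
  # sentence punctuation blocks the cue
  expect_identical(classify_polarity("没有。痛经", 3, lex), "affirmed")
  # cue further than the window does not negate
  far <- paste0("没", paste(rep("天", 7), collapse = ""), "痛经")
  expect_identical(classify_polarity(far, 8, lex), "affirmed")
  # cue ending just inside the window negates
  near <- paste0("没", paste(rep("天", 5), collapse = ""), "痛经")
  expect_identical(classify_polarity(near, 6, lex), "negated")
})

test_that("window assignment implements the five perioperative bins exactly", {
  sdate <- as.Date("2020-06-01")
  offs <- c(-5, -1, 0, 1, 15, 30, 31, 60, 61, 90, 91, 100, 180, 181)
  got <- assign_window(sdate + offs, sdate)
  expect_identical(got, c("PREOP", "PREOP", NA, "M1", "M1", "M1", "M2", "M2",
                          "M3", "M3", "M4_6", "M4_6", "M4_6", NA))
  # total on [-1e4, 180] minus day 0
  all_offs <- setdiff(seq(-1e4, 180), 0)
  expect_false(anyNA(window_of_offset(all_offs)))
})

test_that("identities are extracted, deduplicated and linked to the EHR", {
  st <- make_study(n = 12, seed = 21, noise_rate = 0.2)
  ids <- extract_identities(st$corpus)
  expect_equal(nrow(ids), 12)
  expect_setequal(ids$patient_key, st$cohort$patient_key)
  expect_identical(ids$name[order(ids$patient_key)],
                   st$cohort$name[order(st$cohort$patient_key)])

  # duplicate announcements collapse to one record
  dup <- st$corpus[rep(grep("住院号", st$corpus$text)[1], 2), ]
  expect_equal(nrow(extract_identities(dup)), 1)

  # no identity lines -> empty
  none <- st$corpus[!grepl("住院号", st$corpus$text), ]
  expect_equal(nrow(extract_identities(none)), 0)

  linked <- link_to_ehr(ids, st$cohort)
  expect_equal(nrow(linked$cohort), 12)
  expect_length(linked$unlinked_identities, 0)
  # an identity absent from the EHR is reported, not joined
  ids2 <- rbind(ids, data.frame(patient_key = "H9999", name = "无名",
                                alias = "无名9999"))
  linked2 <- link_to_ehr(ids2, st$cohort)
  expect_equal(nrow(linked2$cohort), 12)
  expect_identical(linked2$unlinked_identities, "H9999")
  # duplicate EHR keys are a data error
  expect_error(link_to_ehr(ids, rbind(st$cohort, st$cohort[1, ])),
               class = "perisym_data_error")
})

test_that("extraction recovers every gold mention on a noise-free corpus", {
  st <- make_study(n = 30, seed = 13, noise_rate = 0.2, negation_rate = 0.2)
  expect_equal(mention_recall(st$corpus, st$gold), 1)
  # and precision: nothing beyond gold
  mm <- detect_corpus_mentions(st$corpus, lex)
  gk <- paste(st$gold$message_id, st$gold$concept_id, st$gold$start,
              st$gold$polarity)
  mk <- paste(mm$message_id, mm$concept_id, mm$start, mm$polarity)
  expect_true(all(mk %in% gk))
})

test_that("presence matrix applies the any-affirmed rule and matches planted prevalence", {
  cohort <- data.frame(patient_key = "P1", stringsAsFactors = FALSE)
  mk <- function(pol, win = "M1") {
    data.frame(patient_key = "P1", concept_id = "dysmenorrhea",
               polarity = pol, window = win, stringsAsFactors = FALSE)
  }
  both <- rbind(mk("affirmed"), mk("negated"))
  pm <- build_presence_matrix(both, cohort, concepts = "dysmenorrhea")
  expect_true(pm$present[pm$window == "M1"])
  # negated-only cell is absent
  pm2 <- build_presence_matrix(mk("negated"), cohort,
                               concepts = "dysmenorrhea")
  expect_false(any(pm2$present))
  # invariant to message order
  pm3 <- build_presence_matrix(both[2:1, ], cohort,
                               concepts = "dysmenorrhea")
  expect_equal(pm$present, pm3$present)

  # gold-derived and extracted presence agree on a noise-free corpus
  st <- make_study(n = 25, seed = 17, noise_rate = 0.2)
  ids <- extract_identities(st$corpus)
  linked <- link_to_ehr(ids, st$cohort)
  mm <- detect_corpus_mentions(st$corpus, lex, linked$cohort)
  pm_ext <- build_presence_matrix(mm, linked$cohort,
                                  concepts = names(lex$terms))
  pm_gold <- build_presence_matrix(st$gold, linked$cohort,
                                   concepts = names(lex$terms))
  expect_equal(pm_ext$present, pm_gold$present)
})

test_that("unknown patients in mentions are dropped with a warning", {
  cohort <- data.frame(patient_key = "P1", stringsAsFactors = FALSE)
  mm <- data.frame(patient_key = c("P1", "PX"), concept_id = "dizziness",
                   polarity = "affirmed", window = "M2",
                   stringsAsFactors = FALSE)
  expect_warning(pm <- build_presence_matrix(mm, cohort), "unknown")
  expect_equal(sum(pm$present), 1)
})

test_that("first postoperative report times are per-patient minima, then medians", {
  cohort <- data.frame(patient_key = c("P1", "P2", "P3"),
                       stringsAsFactors = FALSE)
  mm <- data.frame(
    patient_key = c("P1", "P1", "P2", "P3", "P3"),
    concept_id = "dysmenorrhea",
    polarity = c("affirmed", "affirmed", "affirmed", "affirmed", "negated"),
    day_offset = c(30, 2, 18, 30, 1),
    stringsAsFactors = FALSE
  )
  out <- first_report_times(mm, cohort)
  # planted first-mention days {2, 18, 30} -> median 18
  expect_equal(out$median_day, 18)
  expect_equal(out$n_patients, 3L)
  # single patient: the median is that patient's first day
  one <- first_report_times(mm[mm$patient_key == "P2", ], cohort)
  expect_equal(one$median_day, 18)
  # preoperative mentions never count
  pre <- data.frame(patient_key = "P1", concept_id = "fatigue",
                    polarity = "affirmed", day_offset = -10,
                    stringsAsFactors = FALSE)
  expect_true(is.na(first_report_times(pre, cohort)$median_day))
})

test_that("recall degrades monotonically with the OCR corruption rate", {
  st <- make_study(n = 60, seed = 29, noise_rate = 0.1, negation_rate = 0.15)
  for (s in c(1, 2, 3)) {
    rec <- vapply(c(0, 0.02, 0.05), function(r) {
      mention_recall(corrupt_corpus(st$corpus, r, seed = s), st$gold)
    }, 0)
    expect_equal(rec[1], 1)
    expect_true(all(diff(rec) <= 0),
                label = paste("monotone recall, seed", s))
    expect_lt(rec[3], 1)
  }
})
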