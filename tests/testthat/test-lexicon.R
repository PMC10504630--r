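test_that("the shipped lexicon loads with 11 concepts and validates", {
  lex <- load_lexicon()
  terms <- lex[lex$kind == "term", ]
  expect_length(unique(terms$concept_id), 11)
  expect_setequal(unique(terms$concept_id), PERISYM_CONCEPTS)
  expect_gt(sum(lex$kind == "negation_cue"), 0)
  # stronger shipped-file invariant: no term of one concept is a substring
  # of a term of another (keeps gold round-trips exact)
  for (i in seq_len(nrow(terms))) {
    inside <- vapply(terms$surface_term, grepl, logical(1),
                     x = terms$surface_term[i], fixed = TRUE)
    expect_true(all(terms$concept_id[inside] == terms$concept_id[i]),
                label = paste("cross-concept containment for",
                              terms$surface_term[i]))
  }
})

test_that("lexicon validation names duplicate and empty terms", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("concept_id\tsurface_term\tkind",
               "dysmenorrhea\t痛经\tterm",
               "menorrhagia\t痛经\tterm"), tmp)
  expect_error(load_lexicon(tmp), "痛经", class = "perisym_config_error")

  writeLines(c("concept_id\tsurface_term\tkind",
               "dysmenorrhea\t\tterm"), tmp)
  expect_error(load_lexicon(tmp), class = "perisym_config_error")

  writeLines("concept_id\tsurface_term\tkind", tmp)
  expect_warning(empty <- load_lexicon(tmp), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("compilation orders terms longest-first and matches every shipped term", {
  entries <- data.frame(concept_id = "menorrhagia",
                        surface_term = c("经量多", "月经量多"),
                        kind = "term", stringsAsFactors = FALSE)
  lex <- compile_lexicon(entries, negation_cues = character())
  expect_identical(lex$terms$menorrhagia, c("月经量多", "经量多"))

  empty <- compile_lexicon(data.frame(concept_id = character(),
                                      surface_term = character(),
                                      kind = character()))
  expect_equal(nrow(detect_mentions("月经量多", empty)), 0)

  # self-match oracle: every shipped term matches itself as a standalone text
  lex <- shipped_lexicon()
  for (cc in names(lex$terms)) {
    for (term in lex$terms[[cc]]) {
      mm <- detect_mentions(term, lex)
      hit <- mm[mm$concept_id == cc, ]
      expect_true(any(hit$start == 0 & hit$end == nchar(term)),
                  label = paste("self-match of", term))
    }
  }
  expect_error(compile_lexicon(load_lexicon(), negation_window = 0),
               class = "perisym_config_error")
})

test_that("pruning removes unseen terms, reports counts, and preserves training matches", {
  lex <- shipped_lexicon()
  train <- data.frame(text = c("这几天痛经了", "月经量多，还有痛经"),
                      stringsAsFactors = FALSE)
  pr <- prune_lexicon(lex, train)
  expect_setequal(names(pr$lexicon$terms), c("dysmenorrhea", "menorrhagia"))
  expect_identical(pr$lexicon$terms$dysmenorrhea, "痛经")
  # report counts equal a brute-force scan
  expect_equal(pr$report$train_count[pr$report$term == "痛经"], 2L)
  expect_equal(pr$report$train_count[pr$report$term == "月经量多"], 1L)
  expect_true(all(pr$report$kept == (pr$report$train_count > 0)))
  # monotone: pruned terms are a subset; empty concepts reported not dropped
  expect_true(all(unlist(pr$lexicon$terms) %in% unlist(lex$terms)))
  expect_setequal(pr$empty_concepts,
                  setdiff(names(lex$terms), names(pr$lexicon$terms)))
  # matches of the pruned lexicon on the training corpus equal the original
  for (tx in train$text) {
    a <- detect_mentions(tx, lex); b <- detect_mentions(tx, pr$lexicon)
    expect_setequal(paste(a$concept_id, a$start, a$end),
                    paste(b$concept_id, b$start, b$end))
  }
  # all-present corpus leaves the lexicon unchanged
  full <- data.frame(text = unlist(lex$terms), stringsAsFactors = FALSE)
  pr2 <- prune_lexicon(lex, full)
  expect_identical(pr2$lexicon$terms[names(lex$terms)], lex$terms)
})
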