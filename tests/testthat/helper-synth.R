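# Shared fixtures: every corpus is generated in code at test time.

shipped_lexicon <- function() compile_lexicon(load_lexicon())

# A small noise-free study whose planted mentions a perfect extractor
# recovers exactly.
make_study <- function(n = 20, seed = 42, noise_rate = 0,
                       negation_rate = 0.15, ocr_noise_rate = 0,
                       prevalence = default_prevalence()) {
  cfg <- cohort_config(n_patients = n, seed = seed, noise_rate = noise_rate,
                       negation_rate = negation_rate,
                       ocr_noise_rate = ocr_noise_rate,
                       prevalence = prevalence)
  cohort <- generate_cohort(cfg)
  chat <- generate_chat(cohort, cfg)
  list(config = cfg, cohort = cohort, corpus = chat$corpus, gold = chat$gold)
}

# Mention-level recall of extraction against gold labels, matching on
# (message_id, concept, start, polarity).
mention_recall <- function(corpus, gold, lex = shipped_lexicon()) {
  mm <- detect_corpus_mentions(corpus, lex)
  gk <- paste(gold$message_id, gold$concept_id, gold$start, gold$polarity)
  mk <- paste(mm$message_id, mm$concept_id, mm$start, mm$polarity)
  mean(gk %in% mk)
}
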