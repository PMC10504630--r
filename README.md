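# perisym

Rule-based symptom mining and perioperative burden statistics for
clinician–patient chat text.

## The problem

Patients recovering from focused ultrasound ablation surgery (FUAS) for
uterine fibroids rarely fill in questionnaires, but they do tell their
clinicians how they feel — in Chinese group chats, in short unstructured
messages ("这几天经量多了", "现在没有痛经了"). `perisym` turns such
transcripts into an analysable patient × symptom × time-window presence
matrix and runs the statistical battery of perioperative symptom
epidemiology on it. It is written for biostatisticians and clinical NLP
researchers who need a transparent, fully rule-based alternative to
black-box extraction: every decision the pipeline makes can be traced to a
lexicon row or a negation rule.

The pipeline:

1. **Cleaning** — keep senders whose messages concern fibroids
   (keyword filter at the *sender* level), strip emoji, URLs, pasted lab
   reports and low-value tokens; split patients 30/70 into
   lexicon-training and validation sets.
2. **Lexicon** — 11 symptom concepts (menorrhagia, dysmenorrhea,
   prolonged menstrual period, blood clots, dizziness, fatigue, lower
   abdominal pain, menstrual disorder, vaginal secretion, intensified
   dysmenorrhea, frequent urination), each with several Chinese surface
   terms plus global negation cues; terms never seen in the training
   corpus are pruned.
3. **Extraction** — longest-first substring matching per concept;
   a mention is *negated* iff a negation cue ends within 6 characters
   before it with no sentence punctuation in between; patient identity is
   parsed from self-introduction lines and linked to an EHR table; each
   message is binned into one of 5 perioperative windows (PREOP, months
   1, 2, 3, 4–6 after surgery, day 0 excluded).
4. **Agreement** — Cohen's κ = (p_o − p_e)/(1 − p_e) against gold
   labels at the patient–window–concept level, with discordance listings
   for adjudication (κ 0.61–0.80 "good", 0.81–1.00 "excellent").
5. **Statistics** — uncorrected Pearson χ² = N(ad − bc)²/((a+b)(c+d)(a+c)(b+d))
   for pre/post prevalence; cross-product odds ratios OR = ad/bc with
   Wald 95% CIs; Bonferroni cutoffs α/k; logistic GEE prevalence
   trajectories (exchangeable working correlation, robust sandwich SEs)
   with a linear time index over the five windows; and piecewise trends
   around the 1-month knot.
6. **Synthetic data** — because real clinician–patient chats are
   private, a generator plants symptom mentions at configurable
   prevalence with exact gold spans, explicit denials, off-topic noise
   and OCR-style character corruption, so the whole pipeline is testable
   end to end.

## Worked example

Simulate a 408-patient study, run the full pipeline against its own gold
annotations, and reproduce published 2×2 statistics from printed counts:

```r
library(perisym)

cfg    <- cohort_config(n_patients = 408, seed = 1,
                        noise_rate = 0.2, negation_rate = 0.15)
cohort <- generate_cohort(cfg)
chat   <- generate_chat(cohort, cfg)
res    <- run_pipeline(chat$corpus, cohort, gold = chat$gold,
                       prune = FALSE, quiet = TRUE)

res$kappa
#> Cohen's kappa = 1.0000 (excellent); p_o = 1.0000, p_e = 0.9165, n = 22440

head(res$table2[order(-res$table2$chi2),
                c("concept_id", "n_pre", "n_post", "chi2", "p")], 3)
#>          concept_id n_pre n_post   chi2         p
#> 7       menorrhagia   139     21 108.25 2.369e-25
#> 11 vaginal_secretion     0     60  64.76 8.452e-16
#> 2      dysmenorrhea   139     59  42.68 6.449e-11

pearson_chi2(two_by_two(137, 271, 17, 391))   # printed pre/post counts
#> chi-square = 115.259 (df = 1), p = 6.91e-27

odds_ratio(two_by_two(58, 151, 77, 111))      # age > 40 vs dysmenorrhea
#> OR 0.55, 95% CI 0.36-0.84
```

The κ of 1 says the extractor recovered every planted presence decision on
a noise-free corpus (22 440 = 408 patients × 11 concepts × 5 windows).
The χ² table shows the simulated cohort reproducing the planted pattern:
bleeding-type symptoms collapse after surgery while vaginal secretion and
menstrual disorder emerge as treatment-related symptoms. The last two
calls compute a pre/post χ² and a risk-screen odds ratio directly from
printed 2×2 counts.

A command-line wrapper is included:

```sh
Rscript inst/scripts/perisym.R simulate --out simdir --n 408 --seed 1
Rscript inst/scripts/perisym.R run --chat simdir/chat.jsonl \
    --ehr simdir/ehr.csv --gold simdir/gold.jsonl --out results
```

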