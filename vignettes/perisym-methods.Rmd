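---
title: "Methods: rule-based symptom mining and perioperative trajectory models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based symptom mining and perioperative trajectory models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`perisym` extracts patient-reported symptoms of uterine fibroids from
Chinese clinician–patient chat transcripts and analyses their
perioperative trajectories. This vignette explains the model behind each
stage, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the design decisions taken where the problem
left them open.

## The extraction model

Extraction is deliberately rule-based. The unit of meaning is a
**surface term**: a fixed Chinese string (e.g. 月经量多, 痛经) mapped to
one of 11 **symptom concepts**. The lexicon ships as a one-row-per-variant
table (`inst/extdata/symptom_lexicon_zh.tsv`), which doubles as the
normalization mapping from surface variant to concept. It is a
representative, synthetic lexicon written for this package: it covers the
concept inventory of the fibroid domain but makes no claim to reproduce
any specific clinical group's internal term list.

**Matching** is plain substring search without word segmentation. Chinese
has no whitespace tokens, and segmenters disagree on exactly the short,
colloquial strings that matter here; a fixed-string match is transparent
and auditable. Within a concept, terms are tried longest first and
overlapping shorter matches are suppressed, so 月经量多 wins over its
substring 经量多 at the same position. Matches of *different* concepts may
overlap — suppressing them would silently create precedence rules between
concepts that nothing in the domain justifies. The shipped lexicon
additionally guarantees that no term of one concept is a substring of a
term of another, so in practice cross-concept overlaps do not arise with
the default resource.

**Negation** follows the classic bounded look-back of rule-based clinical
NLP: a mention is negated iff a negation cue (没有, 没, 无, 不, 未, …)
ends within `negation_window` characters *before* the match start, with no
sentence punctuation (。！？；，) in between. The default window is 6
characters: Chinese negation almost always immediately precedes the
negated predicate (没有痛经, 复查未见血块), and a short window avoids
false negations from unrelated clauses. Cues after a term never negate it
(痛经好了没有来月经 affirms the dysmenorrhea). This is an asymmetric,
precision-oriented rule; it will miss rare postposed negation.

**Identity linkage.** Patients announce themselves in a fixed
self-introduction pattern (name plus admission number). The extractor
parses these lines, deduplicates them (first occurrence wins on
conflicting names), and inner-joins the keys against the EHR table.
Mentions are attributed to patients through the announcing sender's chat
alias. Real chat data would need a richer battery of identity patterns;
the pattern set is a single shared constant so that extending it extends
generator and extractor together.

**Time binning.** Day offsets from the surgery date map to five analysis
windows: PREOP (offset < 0), M1 (1–30), M2 (31–60), M3 (61–90), M4_6
(91–180). Day 0 is excluded from all windows — the analysis contrasts
"before" with "after", and the surgery day belongs to neither — and
offsets beyond 180 days are outside the study horizon. The
patient-level **presence matrix** sets a cell true iff the patient has at
least one *affirmed* mention of the concept in the window. Where an
affirmed and a negated mention co-occur in a cell, the affirmed one wins:
prevalence is "did the patient report this at some point in the window",
and a denial elsewhere in the window does not erase a report.

## Agreement

Automated extraction is scored against gold labels with Cohen's
κ = (p_o − p_e)/(1 − p_e) at the patient–window–concept level — the level
at which the statistics consume the data — rather than at the character
span level, which would punish boundary disagreements that have no
analytical consequence. κ is undefined when both label sets are constant
(p_e = 1); the implementation raises a diagnostic error instead of
returning a misleading number. Bands follow the published convention:
0.61–0.80 good, 0.81–1.00 excellent.

## The statistical battery

**Pre/post prevalence.** For each concept, preoperative and postoperative
presence counts over the same N patients form a 2×2 table whose rows are
treated as independent margins, tested with the *uncorrected* Pearson
χ² = N(ad − bc)²/((a+b)(c+d)(a+c)(b+d)), df = 1. Two choices deserve
comment. First, no Yates continuity correction: the uncorrected statistic
is the one this literature prints, and the correction is known to be
conservative at these sample sizes. Second, the unpaired rather than
McNemar's paired test: pairing would need discordant-pair counts that a
prevalence table does not carry, and the printed statistics of the tables
this machinery mirrors are reproducible only under the unpaired formula.
Postoperative presence aggregates the four postoperative windows with a
logical OR, giving a single pre vs post contrast.

**Odds ratios.** Risk screens use the cross-product OR = ad/bc with the
Wald interval exp(ln OR ± z√(1/a+1/b+1/c+1/d)), z = 1.96. A zero cell is
an error that points the user to the Haldane–Anscombe correction rather
than silently applying it. Exposure orientation is fixed per factor in
the screen configuration (age > 40, BMI ≥ 24 kg/m², pregnancies ≥ 2,
abortions ≥ 2, parity > 1) so that reported directions are stable.
Multiplicity is handled with the Bonferroni cutoff α/k over the k factors
screened.

**Trajectories.** Symptom presence over the five windows is a repeated
binary outcome, modelled marginally with a logistic GEE: logit
P(present) = β₀ + β₁·t with t the window index 0–4, clustered on the
patient, exchangeable working correlation, and robust (sandwich) standard
errors. Because no GEE implementation is available to the package's
dependency set, the estimator is implemented here directly: Fisher
scoring on the GEE score equations, a moment estimator for the common
working correlation α from Pearson residual cross-products, and the
standard sandwich covariance at convergence. The implementation is
validated two ways in the test suite: with singleton clusters and an
independence working structure it must reproduce `stats::glm` logistic
estimates to 10⁻⁶, and planted trajectory slopes must be covered by the
robust 95% Wald interval in ≥ 90% of simulations (100 cohorts of 2000
patients × 5 windows).

**Piecewise trends.** Some symptoms fall to a floor by the first
postoperative month; others peak there. A single linear trend misses
both, so the package fits two segment models around the M1 knot — PREOP→M1
and M1→M4_6, each a GEE on the sub-range with time re-indexed from zero.
This phrases the "two-phase" trajectory analysis entirely within the GEE
framework rather than as a random-coefficient mixed model; for marginal
prevalence statements the two coincide in interpretation, and the GEE
route keeps the estimand identical to the single-trend model.

**Postoperative risk screen.** Per concept, a GEE of postoperative
presence (M1–M4_6) on the time index plus all dichotomized baseline
factors; each factor's coefficient is reported with its robust SE and a
Bonferroni flag at α/k. Coefficients are log-odds scale estimates, not
odds ratios — exponentiation is left to the reader because the screen's
purpose is flagging, not effect communication.

## What the generator emulates — and what it does not

The synthetic-data module exists because real clinician–patient chats are
private. Its defaults *are* the study conditions of the cohort the
package models: 408 patients; preoperative prevalences per concept equal
to published cohort values (e.g. dysmenorrhea 33.1%, menorrhagia 33.6%,
vaginal secretion 0%); per-window postoperative probabilities solved so
that their union over the four windows equals the published overall
postoperative prevalence, p_w = 1 − (1 − P_post)^(1/4); baseline EHR
variables drawn from published means and SDs (age 39.94 (6.81) years;
BMI from the plausible 22.18 (2.78) kg/m² rather than a typographically
corrupted alternative); surgery dates uniform over 2010–2020.

Per patient and window, one Bernoulli draw per concept decides affirmed
presence; a symptom absent from a window is explicitly denied with
probability `negation_rate` (default 0.15 in examples, 0.10 in the
config default). Off-topic chatter and clinician replies are interleaved
so that noise makes up `noise_rate` of messages in expectation. Message
timestamps are uniform within each window (the preoperative window spans
`preop_days` = 60 days before surgery) because no message-time
distribution is documented; message volume per patient is therefore an
emergent parameter, not a calibrated one. Messages are template-based —
prefix + term + suffix with exact recorded spans — which is what makes
gold labels exact and the κ = 1 round-trip a meaningful oracle.

OCR-style corruption replaces each character independently with
probability `ocr_noise_rate` by a visually confusable partner from a
fixed ~50-pair table of similar Chinese characters (己/已, 经/径, 血/皿,
…), falling back to an unknown-glyph box. One uniform draw per character
against a per-message seed means the corruption set at a lower rate is a
subset of the set at any higher rate, so extraction recall is monotone in
the rate *by construction* — the monotonicity test verifies the pipeline,
not the luck of the draw.

What passing these tests does **not** show about real data: templates
cannot produce free word order, typos, dialect, emoji-laden sarcasm,
coreference ("又来了"), or symptom descriptions that paraphrase rather
than name; real OCR errors are burstier than independent per-character
flips; and real identity lines are messier than one fixed pattern. A κ of
1 on synthetic data certifies the machinery, not field performance.

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open; dates are ISO-8601.
* Determinism: every stochastic function takes a seed; the generator
  splits one base seed per patient by counter, so identical (config,
  seed) give byte-identical corpora, gold sets and EHR tables.
* Seeds derived internally stay below 2³¹ (32-bit R integers).
* GEE: starts at the logistic fit, caps |α| at 0.99, stops when the
  largest coefficient step falls below 10⁻⁹, and raises an error carrying
  the step trace if 50 iterations do not converge.
* χ² with a zero marginal, κ with constant raters, ORs with zero cells,
  splits with fewer than two patients, and GEE segments with no data all
  raise typed errors (`perisym_config_error` / `perisym_data_error`)
  rather than returning NaN.
* Whitespace collapsing during cleaning keeps the first whitespace
  character of each run, so cleaning can never introduce a character the
  message did not contain.
* Cleaning is idempotent on realistic text; pathological inputs built to
  recreate a stop token from its own fragments (e.g. 早早上上) can defeat
  a single pass and are accepted as out of scope.
* Lexicon pruning counts overlapping occurrences and never silently drops
  a concept — concepts whose whole term set is unseen in training are
  reported in the prune report.

## Problem sizes in the test suite

The suite generates all fixtures in code. Typical scales, chosen to keep
binomial/simulation error well below the tested tolerances while the full
suite runs in well under two minutes: prevalence fidelity at n = 5000
patients (3 binomial SEs), age distribution at n = 10 000, end-to-end
agreement at the study scale of n = 408, GEE coverage at 100 replicates
of 2000 patients × 5 windows, χ² oracle agreement over 1000 random
tables at 10⁻⁹.

## Known limitations

* Sender-level keyword inclusion (keep *all* messages of any sender who
  ever mentions a fibroid keyword) is a documented interpretation choice;
  message-level filtering would discard symptom reports that do not
  repeat the word "fibroid", but sender-level inclusion can admit a
  sender whose fibroid mention was incidental.
* Clinician messages are excluded from mention detection by default
  (`include_clinician = FALSE`): whether a clinician's "你还有痛经吗" should
  count as a patient symptom report is doubtful, but the flag exists.
* No severity grading, no coreference, no simplified/traditional
  conversion, no spelling correction.
* The presence matrix treats a window with no messages as "absent", which
  conflates "did not report" with "was not asked / did not write"; a
  missingness-aware extension would need message-volume covariates.
* Table-4-style statistics (association of preoperative dysmenorrhea
  with each postoperative symptom via an unidentifiable test statistic)
  are not implemented; the 2×2 machinery covers the identifiable part.
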