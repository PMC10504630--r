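Package: perisym
Title: Rule-Based Symptom Mining and Perioperative Burden Statistics for
    Clinician-Patient Chat Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts patient-reported symptoms of uterine fibroids from
    Chinese clinician-patient group-chat transcripts with a rule-based
    pipeline (symptom lexicon, longest-first pattern matching, pre-term
    negation detection, perioperative time-window binning, and linkage to
    an electronic health record table), and analyses the resulting
    patient x symptom x window presence matrix with the perioperative
    statistical battery used in symptom epidemiology: pre/post prevalence
    chi-square tests, odds-ratio risk screens with Wald intervals,
    Bonferroni-adjusted cutoffs, generalized estimating equation (GEE)
    prevalence trajectories with robust standard errors, and piecewise
    trend models around the one-month postoperative knot. A synthetic
    chat/EHR generator with gold annotations makes every stage testable
    without access to private messaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
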