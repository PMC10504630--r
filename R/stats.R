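# Perioperative symptom-burden statistics: 2x2 prevalence tests, odds
# ratios, baseline comparisons, Bonferroni screening.

#' A labelled 2x2 contingency table
#'
#' Cell layout: rows are group (or time point, or exposure level), columns
#' are outcome present/absent:
#' \preformatted{            present  absent
#'   row1 (a)     a        b
#'   row2 (c)     c        d}
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param labels Optional character vector of length 2 naming the rows.
#' @return Object of class `perisym_2x2`.
#' @export
two_by_two <- function(a, b, c, d, labels = c("row1", "row2")) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop_data("cell counts must be nonnegative")
  }
  if (sum(cells) == 0) stop_data("empty table")
  structure(list(a = a, b = b, c = c, d = d, labels = labels),
            class = "perisym_2x2")
}

#' @export
print.perisym_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(x$labels, c("present", "absent")))
  print(m)
  invisible(x)
}

#' Uncorrected Pearson chi-square test for a 2x2 table
#'
#' Closed form chi^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) with one
#' degree of freedom and no continuity correction: this is the statistic
#' that pre/post prevalence comparisons of independent margins report.
#'
#' @param tab A [two_by_two()] table.
#' @return List of class `perisym_chisq`: `statistic`, `df` (= 1), `p`.
#' @examples
#' pearson_chi2(two_by_two(137, 271, 17, 391))
#' @export
pearson_chi2 <- function(tab) {
  stopifnot(inherits(tab, "perisym_2x2"))
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  N <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    stop_data("chi-square undefined: zero marginal total")
  }
  stat <- N * (a * d - b * c)^2 / prod(marg)
  structure(list(statistic = stat, df = 1L,
                 p = pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "perisym_chisq")
}

#' @export
print.perisym_chisq <- function(x, ...) {
  cat(sprintf("chi-square = %.3f (df = 1), p = %.3g\n", x$statistic, x$p))
  invisible(x)
}

#' Cross-product odds ratio with a Wald confidence interval
#'
#' OR = (a d) / (b c) with rows as exposure levels and columns as outcome,
#' and CI = exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). All four
#' cells must be positive; for tables with a zero cell, add 0.5 to every
#' cell first (Haldane-Anscombe correction) and pass the corrected counts
#' explicitly — the correction is deliberately not applied silently.
#'
#' @param tab A [two_by_two()] table (rows: exposed / unexposed; columns:
#'   outcome present / absent).
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @return List of class `perisym_or`: `or`, `log_or`, `se`, `ci_low`,
#'   `ci_high`, `z`.
#' @examples
#' odds_ratio(two_by_two(58, 151, 77, 111))  # OR 0.55, CI 0.36-0.84
#' @export
odds_ratio <- function(tab, z = 1.96) {
  stopifnot(inherits(tab, "perisym_2x2"))
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells == 0)) {
    stop_data("odds ratio undefined with a zero cell; apply the ",
              "Haldane-Anscombe correction (add 0.5 to each cell) and ",
              "rebuild the table if a corrected estimate is wanted")
  }
  or <- (tab$a * tab$d) / (tab$b * tab$c)
  se <- sqrt(sum(1 / cells))
  structure(list(or = or, log_or = log(or), se = se,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se), z = z),
            class = "perisym_or")
}

#' @export
print.perisym_or <- function(x, ...) {
  cat(sprintf("OR %.2f, %d%% CI %.2f-%.2f\n", x$or,
              round(100 * (1 - 2 * pnorm(-x$z))), x$ci_low, x$ci_high))
  invisible(x)
}

#' Compare a continuous variable between two groups
#'
#' Two-sided t test (Welch by default, pooled on request) or Wilcoxon test
#' (paired rank-sum when `paired = TRUE`).
#'
#' @param x,y Numeric samples.
#' @param method `"t"` or `"wilcoxon"`.
#' @param paired Paired comparison (requires equal lengths).
#' @param pooled For the t test, use the pooled-variance statistic instead
#'   of Welch.
#' @return The `htest` object from [stats::t.test()] or
#'   [stats::wilcox.test()].
#' @export
compare_continuous <- function(x, y, method = c("t", "wilcoxon"),
                               paired = FALSE, pooled = FALSE) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) stop_data("empty sample")
  if (stats::var(x) == 0 && stats::var(y) == 0 && !paired) {
    stop_data("degenerate comparison: both samples have zero variance")
  }
  if (method == "t") {
    stats::t.test(x, y, paired = paired, var.equal = pooled)
  } else {
    if (paired && length(x) == length(y) && all(x == y)) {
      # all paired differences zero: no evidence of a shift by convention
      return(structure(list(statistic = c(V = 0), p.value = 1,
                            method = "Wilcoxon signed rank test",
                            alternative = "two.sided",
                            data.name = "x and y"),
                       class = "htest"))
    }
    stats::wilcox.test(x, y, paired = paired, exact = FALSE, correct = FALSE)
  }
}

#' Bonferroni-adjusted significance cutoff
#'
#' @param alpha Family-wise significance level.
#' @param k Number of risk factors screened (>= 1).
#' @return `alpha / k`.
#' @examples
#' bonferroni_cutoff(0.05, 5)  # 0.01
#' @export
bonferroni_cutoff <- function(alpha = 0.05, k) {
  if (length(k) != 1 || is.na(k) || k < 1) {
    stop_config("k must be a positive integer")
  }
  alpha / k
}

#' Default risk-factor dichotomizations
#'
#' Cutpoints used when screening baseline factors against symptom
#' outcomes: age > 40 years, BMI >= 24 kg/m2, pregnancies >= 2,
#' abortions >= 2, parity > 1. The exposure orientation (which level is
#' the numerator of the odds ratio) is fixed per factor.
#'
#' @return Named list of `list(var, cut, exposure)` entries, where
#'   `exposure` is `">="` or `">"` against `cut`.
#' @export
default_risk_factors <- function() {
  list(
    age = list(var = "age", cut = 40, exposure = ">"),
    bmi = list(var = "bmi", cut = 24, exposure = ">="),
    pregnancy = list(var = "pregnancy", cut = 2, exposure = ">="),
    abortion = list(var = "abortion", cut = 2, exposure = ">="),
    parity = list(var = "parity", cut = 1, exposure = ">")
  )
}

dichotomize <- function(x, spec) {
  if (spec$exposure == ">=") x >= spec$cut else x > spec$cut
}

#' Screen baseline risk factors against a binary outcome
#'
#' For each dichotomized factor, builds the exposed/unexposed vs outcome
#' 2x2 table and reports the uncorrected chi-square p-value and the
#' cross-product odds ratio with its Wald interval, flagging factors that
#' pass the Bonferroni-adjusted cutoff alpha / k. Factors with a single
#' observed level are skipped with a warning.
#'
#' @param ehr EHR data frame (one row per patient).
#' @param outcome Logical vector aligned with `ehr` rows (e.g. preoperative
#'   dysmenorrhea presence).
#' @param factors Factor specification, see [default_risk_factors()].
#' @param alpha Family-wise significance level.
#' @return Data frame, one row per factor: `factor`, `exposure`, `a`-`d`
#'   cell counts, `chi2`, `p`, `or`, `ci_low`, `ci_high`, `cutoff`,
#'   `significant`.
#' @export
risk_factor_screen <- function(ehr, outcome,
                               factors = default_risk_factors(),
                               alpha = 0.05) {
  stopifnot(length(outcome) == nrow(ehr))
  k <- length(factors)
  cutoff <- bonferroni_cutoff(alpha, k)
  rows <- list()
  for (nm in names(factors)) {
    spec <- factors[[nm]]
    xv <- ehr[[spec$var]]
    ok <- !is.na(xv) & !is.na(outcome)
    exposed <- dichotomize(xv[ok], spec)
    out <- outcome[ok]
    if (length(unique(exposed)) < 2) {
      warning("factor '", nm, "' has a single level; skipped")
      next
    }
    tab <- two_by_two(sum(exposed & out), sum(exposed & !out),
                      sum(!exposed & out), sum(!exposed & !out),
                      labels = c(paste0(spec$var, spec$exposure, spec$cut),
                                 "unexposed"))
    chi <- pearson_chi2(tab)
    or <- tryCatch(odds_ratio(tab), error = function(e) NULL)
    rows[[nm]] <- data.frame(
      factor = nm,
      exposure = paste0(spec$var, " ", spec$exposure, " ", spec$cut),
      a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      chi2 = chi$statistic, p = chi$p,
      or = if (is.null(or)) NA_real_ else or$or,
      ci_low = if (is.null(or)) NA_real_ else or$ci_low,
      ci_high = if (is.null(or)) NA_real_ else or$ci_high,
      cutoff = cutoff,
      significant = chi$p < cutoff,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' GEE screen of risk factors for postoperative symptoms
#'
#' For each symptom concept, fits a logistic GEE of postoperative presence
#' (windows M1-M4_6) on the time index plus all dichotomized factors, and
#' reports each factor's coefficient, robust SE and p-value with a
#' Bonferroni flag at alpha / k.
#'
#' @param pm Presence matrix from [build_presence_matrix()].
#' @param ehr EHR data frame (one row per patient, `patient_key`).
#' @param factors Factor specification, see [default_risk_factors()].
#' @param alpha Family-wise significance level.
#' @return Data frame: `concept_id`, `factor`, `estimate`, `se`, `p`,
#'   `cutoff`, `significant`.
#' @export
postop_gee_screen <- function(pm, ehr, factors = default_risk_factors(),
                              alpha = 0.05) {
  k <- length(factors)
  cutoff <- bonferroni_cutoff(alpha, k)
  cov <- data.frame(patient_key = ehr$patient_key, stringsAsFactors = FALSE)
  for (nm in names(factors)) {
    spec <- factors[[nm]]
    cov[[nm]] <- as.numeric(dichotomize(ehr[[spec$var]], spec))
  }
  cov <- cov[complete.cases(cov), , drop = FALSE]
  post <- pm[pm$window != "PREOP" & pm$patient_key %in% cov$patient_key, ,
             drop = FALSE]
  rows <- list()
  for (cc in unique(post$concept_id)) {
    sub <- post[post$concept_id == cc, , drop = FALSE]
    if (length(unique(sub$present)) < 2) next  # never or always present
    fit <- tryCatch(gee_trend(sub, covariates = cov),
                    error = function(e) NULL)
    if (is.null(fit)) next
    for (nm in names(factors)) {
      rows[[paste(cc, nm)]] <- data.frame(
        concept_id = cc, factor = nm,
        estimate = unname(fit$coefficients[nm]),
        se = unname(fit$robust_se[nm]),
        p = unname(fit$p[nm]),
        cutoff = cutoff,
        significant = unname(fit$p[nm]) < cutoff,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pre/post prevalence chi-square table
#'
#' Builds, for each concept, the 2x2 table of preoperative vs postoperative
#' presence counts over a cohort of size N (two independent margins) and
#' applies the uncorrected Pearson chi-square.
#'
#' @param prepost Data frame `concept_id`, `n_pre`, `n_post`, `N`, e.g.
#'   from [presence_prepost()].
#' @return Data frame with prevalence percentages, chi-square and p per
#'   concept.
#' @export
prepost_chi2_table <- function(prepost) {
  rows <- lapply(seq_len(nrow(prepost)), function(i) {
    r <- prepost[i, ]
    tab <- two_by_two(r$n_pre, r$N - r$n_pre, r$n_post, r$N - r$n_post,
                      labels = c("preoperative", "postoperative"))
    chi <- pearson_chi2(tab)
    data.frame(concept_id = r$concept_id,
               n_pre = r$n_pre, pct_pre = round(100 * r$n_pre / r$N, 1),
               n_post = r$n_post, pct_post = round(100 * r$n_post / r$N, 1),
               chi2 = chi$statistic, df = 1L, p = chi$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
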