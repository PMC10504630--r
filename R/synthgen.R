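# Synthetic clinician-patient chat generator.
#
# Emulates the data source the pipeline is built for: short Chinese
# messages in perioperative follow-up group chats, with symptom terms
# planted at configurable per-window prevalence, explicit denials, identity
# self-introductions, off-topic chatter, clinician replies, and OCR-style
# character corruption. Every planted mention is recorded in a gold label
# set with exact character spans, so extraction can be scored without any
# manual annotation.

# ---- fixed building blocks ------------------------------------------------

SURNAMES <- c("王", "李", "张", "刘", "陈", "杨", "赵", "黄", "周", "吴")
GIVEN <- c("芳", "娟", "敏", "静", "丽", "霞", "燕", "玲", "娜", "婷",
           "秀英", "桂兰", "晓梅", "雪", "倩")

# Affirmed-mention templates: prefix + term + suffix. Prefixes must not end
# in a negation cue (the polarity rule looks back 6 characters).
AFFIRM_PREFIX <- c("最近", "这几天", "术后", "感觉", "这两天")
AFFIRM_SUFFIX <- c("了", "，怎么办", "，正常吗", "，要紧吗", "")

# Negated-mention templates: prefix + cue + term + suffix.
NEGATE_PREFIX <- c("", "现在", "复查", "术后")
NEGATE_CUE <- c("没有", "没再", "不再", "未见")
NEGATE_SUFFIX <- c("了", "")

NOISE_TEMPLATES <- c("今天天气真好", "谢谢医生", "收到，谢谢", "好的，知道了",
                     "请问下周门诊是哪天", "大家周末愉快", "孩子放假了真热闹",
                     "刚出门买菜回来")
CLINICIAN_TEMPLATES <- c("注意休息，按时复查", "多喝水，观察几天看看",
                         "有情况随时在群里说")

IDENTITY_PREFIX <- "我是"
IDENTITY_MID <- "，住院号"
IDENTITY_SUFFIX <- "，子宫肌瘤术后随访"
# kept in sync with extract_identities()
IDENTITY_PATTERN <- "我是(.{2,4})，住院号([A-Z][0-9]{3,})"

# Visually-confusable Chinese character pairs used to emulate residual OCR
# errors; characters outside the table fall back to the unknown-glyph box.
OCR_CONFUSION <- c(
  "己" = "已", "已" = "己", "未" = "末",
  "末" = "未", "土" = "士", "士" = "土",
  "人" = "入", "入" = "人", "日" = "曰",
  "曰" = "日", "天" = "夭", "夭" = "天",
  "王" = "玉", "玉" = "王", "大" = "太",
  "太" = "大", "木" = "本", "本" = "木",
  "白" = "自", "自" = "白", "月" = "目",
  "目" = "月", "干" = "千", "千" = "干",
  "万" = "方", "方" = "万", "午" = "牛",
  "牛" = "午", "头" = "买", "买" = "头",
  "多" = "夕", "夕" = "多", "块" = "快",
  "快" = "块", "经" = "径", "径" = "经",
  "痛" = "捅", "捅" = "痛", "晕" = "军",
  "军" = "晕", "乏" = "泛", "泛" = "乏",
  "力" = "刀", "刀" = "力", "气" = "汽",
  "汽" = "气", "腹" = "复", "复" = "腹",
  "小" = "少", "少" = "小", "肚" = "杜",
  "杜" = "肚", "带" = "常", "常" = "带",
  "分" = "份", "份" = "分", "泌" = "秘",
  "秘" = "泌", "物" = "勿", "勿" = "物",
  "尿" = "尾", "尾" = "尿", "频" = "烦",
  "烦" = "频", "血" = "皿", "皿" = "血",
  "水" = "永", "永" = "水", "期" = "斯",
  "斯" = "期", "延" = "廷", "廷" = "延",
  "长" = "张", "张" = "长", "调" = "周",
  "周" = "调", "紊" = "素", "素" = "紊",
  "乱" = "乳", "乳" = "乱", "提" = "题",
  "题" = "提", "推" = "准", "准" = "推",
  "迟" = "尺", "尺" = "迟"
)

# Day-offset ranges per window relative to the surgery date (day 0 excluded).
WINDOW_RANGES <- list(PREOP = c(-60L, -1L), M1 = c(1L, 30L), M2 = c(31L, 60L),
                      M3 = c(61L, 90L), M4_6 = c(91L, 180L))

# ---- configuration --------------------------------------------------------

#' Default planted prevalence map
#'
#' Per-concept, per-window probabilities that a patient affirms the symptom
#' in at least one message of that window. Preoperative values follow the
#' prevalences reported for a 408-patient focused-ultrasound-ablation
#' cohort; each postoperative window gets the per-window probability whose
#' union over the four postoperative windows equals the reported overall
#' postoperative prevalence (p_w = 1 - (1 - P)^(1/4)).
#'
#' @return Named list: concept -> named numeric vector over
#'   `PERISYM_WINDOWS`.
#' @export
default_prevalence <- function() {
  pw <- function(P) 1 - (1 - P)^(1 / 4)
  spec <- list(  # c(preop overall, postop overall)
    menorrhagia = c(0.336, 0.042),
    dysmenorrhea = c(0.331, 0.157),
    prolonged_menstrual_period = c(0.211, 0.083),
    menstrual_blood_clots = c(0.137, 0.069),
    dizziness = c(0.137, 0.025),
    fatigue = c(0.137, 0.025),
    lower_abdominal_pain = c(0.098, 0.081),
    menstrual_disorder = c(0.039, 0.152),
    vaginal_secretion = c(0.000, 0.157),
    intensified_dysmenorrhea = c(0.060, 0.020),
    frequent_urination = c(0.080, 0.020)
  )
  lapply(spec, function(p) {
    setNames(c(p[1], rep(pw(p[2]), 4)), PERISYM_WINDOWS)
  })
}

#' Synthetic cohort configuration
#'
#' Bundles and validates every knob of the synthetic chat/EHR generator.
#' The same configuration and seed always produce byte-identical output.
#'
#' @param n_patients Number of patients (>= 0).
#' @param prevalence Named list concept -> named probability vector over
#'   time windows (missing windows count as 0); see [default_prevalence()].
#' @param negation_rate Probability that a symptom absent in a
#'   patient-window is explicitly denied in a message (a negated mention).
#' @param noise_rate Expected fraction of off-topic messages.
#' @param ocr_noise_rate Per-character probability of OCR-style corruption.
#' @param seed Integer seed; one shared stream split per patient by counter.
#' @param surgery_date_range Character or Date vector of length 2.
#' @param preop_days Length of the preoperative message window in days.
#' @return An object of class `perisym_cohort_config`.
#' @export
cohort_config <- function(n_patients = 408,
                          prevalence = default_prevalence(),
                          negation_rate = 0.10,
                          noise_rate = 0.20,
                          ocr_noise_rate = 0,
                          seed = 1L,
                          surgery_date_range = c("2010-01-01", "2020-12-31"),
                          preop_days = 60L) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 0) {
    stop_config("n_patients must be a nonnegative integer")
  }
  probs <- c(negation_rate, noise_rate, ocr_noise_rate, unlist(prevalence))
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_config("all probabilities must lie in [0, 1]")
  }
  for (cc in names(prevalence)) {
    w <- names(prevalence[[cc]])
    if (is.null(w) || !all(w %in% PERISYM_WINDOWS)) {
      stop_config("prevalence for '", cc, "' must be named by time windows ",
                  paste(PERISYM_WINDOWS, collapse = ", "))
    }
  }
  rng <- as.Date(surgery_date_range)
  if (length(rng) != 2 || any(is.na(rng)) || rng[1] > rng[2]) {
    stop_config("surgery_date_range must be two ordered dates")
  }
  structure(
    list(n_patients = as.integer(n_patients), prevalence = prevalence,
         negation_rate = negation_rate, noise_rate = noise_rate,
         ocr_noise_rate = ocr_noise_rate, seed = as.integer(seed),
         surgery_date_range = rng, preop_days = as.integer(preop_days)),
    class = "perisym_cohort_config"
  )
}

# ---- EHR generation -------------------------------------------------------

#' Generate a synthetic EHR baseline table
#'
#' One row per patient with the baseline variables used by the risk-factor
#' analyses: demographics, obstetric history, menstrual history, fibroid
#' measurements and treatment covariates, plus the surgery date that
#' anchors the perioperative time windows. Continuous variables are drawn
#' from the published cohort means/SDs (age 39.94 (6.81) years, BMI 22.18
#' (2.78) kg/m2, menarche 13.29 (1.51) years, ...) truncated to plausible
#' clinical bounds; counts are Poisson with the published means.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per patient (class `perisym_ehr`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "perisym_cohort_config"))
  n <- config$n_patients
  cols <- c("patient_key", "name", "surgery_date", "age", "bmi", "pregnancy",
            "abortion", "caesarean_section", "parity", "age_menarche",
            "menstrual_period_days", "menstrual_cycle_days", "uf_lr_mm",
            "uf_fb_mm", "uf_length_mm", "length_of_stay", "readmission",
            "uf_location", "employment", "number_of_ufs",
            "dysmenorrhea_extent")
  if (n == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    class(df) <- c("perisym_ehr", class(df))
    return(df)
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  df <- with_seed(derive_seed(config$seed, 0L), {
    dates <- seq(config$surgery_date_range[1], config$surgery_date_range[2],
                 by = "day")
    data.frame(
      patient_key = sprintf("H%04d", seq_len(n)),
      name = paste0(sample(SURNAMES, n, replace = TRUE),
                    sample(GIVEN, n, replace = TRUE)),
      surgery_date = as.character(sample(dates, n, replace = TRUE)),
      age = round(clamp(rnorm(n, 39.94, 6.81), 18, 70)),
      bmi = round(clamp(rnorm(n, 22.18, 2.78), 15, 40), 2),
      pregnancy = rpois(n, 2.36),
      abortion = rpois(n, 1.90),
      caesarean_section = rpois(n, 0.46),
      parity = rpois(n, 0.98),
      age_menarche = round(clamp(rnorm(n, 13.29, 1.51), 9, 18)),
      menstrual_period_days = round(clamp(rnorm(n, 6.13, 2.59), 2, 15)),
      menstrual_cycle_days = round(clamp(rnorm(n, 28.76, 4.07), 20, 45)),
      uf_lr_mm = round(clamp(rnorm(n, 53.8, 17.7), 10, 150), 1),
      uf_fb_mm = round(clamp(rnorm(n, 52.7, 17.9), 10, 150), 1),
      uf_length_mm = round(clamp(rnorm(n, 60.1, 22.0), 10, 200), 1),
      length_of_stay = round(clamp(rnorm(n, 3.10, 1.97), 1, 15)),
      readmission = rbinom(n, 1, 0.108),
      uf_location = sample(c("submucosal", "intramural", "subserosal"), n,
                           replace = TRUE, prob = c(0.057, 0.897, 0.046)),
      employment = sample(c("unemployed", "part_time", "full_time"), n,
                          replace = TRUE, prob = c(0.410, 0.002, 0.588)),
      number_of_ufs = sample(c("single", "multiple"), n, replace = TRUE,
                             prob = c(0.346, 0.654)),
      dysmenorrhea_extent = sample(c("none", "mild", "moderate", "severe"), n,
                                   replace = TRUE,
                                   prob = c(0.689, 0.218, 0.071, 0.022)),
      stringsAsFactors = FALSE
    )
  })
  class(df) <- c("perisym_ehr", class(df))
  df
}

# ---- chat generation ------------------------------------------------------

#' Generate a synthetic chat corpus with gold annotations
#'
#' For every patient and time window, a Bernoulli draw per concept at the
#' configured prevalence decides whether an affirmed mention of that
#' concept is written into a message of the window; symptoms absent from a
#' window are explicitly denied (a negated mention) with probability
#' `negation_rate`. Off-topic patient chatter and clinician replies are
#' interleaved at `noise_rate`, each patient announces their name and
#' admission number once, and `ocr_noise_rate > 0` corrupts characters via
#' [inject_ocr_noise()]. Every planted mention is emitted as a gold label
#' with its exact character span (0-based, half-open), polarity, window and
#' day offset; gold spans refer to the uncorrupted planting positions
#' (corruption preserves length, so spans stay valid).
#'
#' @param cohort EHR table from [generate_cohort()].
#' @param config The same [cohort_config()] used for the cohort.
#' @return List with `corpus` (chat data frame) and `gold` (gold label data
#'   frame: `message_id`, `patient_key`, `concept_id`, `polarity`, `start`,
#'   `end`, `term`, `window`, `day_offset`).
#' @export
generate_chat <- function(cohort, config) {
  stopifnot(inherits(config, "perisym_cohort_config"))
  lex <- compile_lexicon(load_lexicon())
  missing <- setdiff(names(config$prevalence), names(lex$terms))
  if (length(missing) > 0) {
    stop_config("prevalence configured for unknown concept(s): ",
                paste(missing, collapse = ", "))
  }
  if (nrow(cohort) == 0) {
    return(list(corpus = empty_chat_corpus(), gold = empty_gold()))
  }
  concepts <- names(config$prevalence)
  ranges <- WINDOW_RANGES
  ranges$PREOP <- c(-config$preop_days, -1L)

  msgs <- vector("list", nrow(cohort))
  golds <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pk <- cohort$patient_key[i]
    # chat nickname: EHR name plus admission digits, unique per patient
    alias <- paste0(cohort$name[i], sub("^H", "", pk))
    sdate <- as.Date(cohort$surgery_date[i])
    group <- sprintf("g%02d", (i - 1L) %% 20L + 1L)
    res <- with_seed(derive_seed(config$seed, i), {
      text <- character(); role <- character(); off <- integer()
      g_concept <- character(); g_pol <- character(); g_start <- integer()
      g_end <- integer(); g_term <- character(); g_win <- character()
      g_off <- integer(); g_msg <- integer()

      add_msg <- function(tx, rl, day) {
        text[[length(text) + 1L]] <<- tx
        role[[length(role) + 1L]] <<- rl
        off[[length(off) + 1L]] <<- day
      }
      # identity self-introduction early in the preoperative window
      add_msg(paste0(IDENTITY_PREFIX, cohort$name[i], IDENTITY_MID, pk,
                     IDENTITY_SUFFIX),
              "patient", -config$preop_days)

      for (w in PERISYM_WINDOWS) {
        rr <- ranges[[w]]
        for (cc in concepts) {
          p <- unname(config$prevalence[[cc]][w])
          if (is.na(p)) p <- 0
          present <- runif(1) < p
          denied <- !present && runif(1) < config$negation_rate
          if (!present && !denied) next
          day <- as.integer(sample(seq(rr[1], rr[2]), 1))
          term <- sample(lex$terms[[cc]], 1)
          if (present) {
            pre <- sample(AFFIRM_PREFIX, 1)
            suf <- sample(AFFIRM_SUFFIX, 1)
            tx <- paste0(pre, term, suf)
            start <- nchar(pre)
            pol <- "affirmed"
          } else {
            pre <- paste0(sample(NEGATE_PREFIX, 1), sample(NEGATE_CUE, 1))
            suf <- sample(NEGATE_SUFFIX, 1)
            tx <- paste0(pre, term, suf)
            start <- nchar(pre)
            pol <- "negated"
          }
          add_msg(tx, "patient", day)
          k <- length(g_concept) + 1L
          g_concept[k] <- cc; g_pol[k] <- pol
          g_start[k] <- start; g_end[k] <- start + nchar(term)
          g_term[k] <- term; g_win[k] <- w; g_off[k] <- day
          g_msg[k] <- length(text)
        }
      }
      # off-topic chatter and clinician replies
      n_content <- length(text)
      if (config$noise_rate > 0) {
        lam <- config$noise_rate / (1 - config$noise_rate) * n_content
        n_noise <- rpois(1, lam)
        for (j in seq_len(n_noise)) {
          day <- sample(setdiff(seq(ranges$PREOP[1], 180L), 0L), 1)
          if (runif(1) < 0.3) {
            add_msg(sample(CLINICIAN_TEMPLATES, 1), "clinician", day)
          } else {
            add_msg(sample(NOISE_TEMPLATES, 1), "patient", day)
          }
        }
      }
      list(text = text, role = role, off = off,
           gold = list(concept = g_concept, pol = g_pol, start = g_start,
                       end = g_end, term = g_term, win = g_win, off = g_off,
                       msg = g_msg))
    })
    ids <- sprintf("m%05d_%03d", i, seq_along(res$text))
    msgs[[i]] <- data.frame(
      message_id = ids,
      group_id = group,
      sender_role = res$role,
      sender_alias = ifelse(res$role == "clinician", "医生", alias),
      timestamp = as.character(sdate + res$off),
      text = res$text,
      stringsAsFactors = FALSE
    )
    g <- res$gold
    golds[[i]] <- data.frame(
      message_id = ids[g$msg], patient_key = rep(pk, length(g$msg)),
      concept_id = g$concept,
      polarity = g$pol, start = g$start, end = g$end, term = g$term,
      window = g$win, day_offset = g$off, stringsAsFactors = FALSE
    )
  }
  corpus <- do.call(rbind, msgs)
  gold <- do.call(rbind, golds)
  rownames(corpus) <- rownames(gold) <- NULL
  if (config$ocr_noise_rate > 0) {
    corpus <- corrupt_corpus(corpus, config$ocr_noise_rate,
                             derive_seed(config$seed, 987654L))
  }
  list(corpus = corpus, gold = gold)
}

empty_gold <- function() {
  data.frame(message_id = character(), patient_key = character(),
             concept_id = character(), polarity = character(),
             start = integer(), end = integer(), term = character(),
             window = character(), day_offset = integer(),
             stringsAsFactors = FALSE)
}

# ---- OCR corruption -------------------------------------------------------

#' Inject OCR-style character corruption
#'
#' Each character is independently replaced with probability `rate` by a
#' visually confusable character from a fixed confusion table of similar
#' Chinese character pairs; characters without a tabled confusion partner
#' fall back to the unknown-glyph box. Length is always preserved. With a
#' fixed seed, the set of corrupted positions at a lower rate is a subset
#' of the set at a higher rate (one uniform draw per character), so
#' downstream recall degrades monotonically in `rate` by construction.
#'
#' @param text Character vector.
#' @param rate Per-character corruption probability in \[0, 1\].
#' @param seed Integer seed.
#' @return Character vector of the same length and element-wise nchar.
#' @examples
#' inject_ocr_noise("痛经", 1, seed = 1)
#' @export
inject_ocr_noise <- function(text, rate, seed = 1L) {
  if (is.na(rate) || rate < 0 || rate > 1) stop_config("rate must be in [0, 1]")
  if (rate == 0) return(text)
  with_seed(as.integer(seed), {
    vapply(text, function(tx) {
      ch <- strsplit(tx, "", fixed = TRUE)[[1]]
      if (length(ch) == 0) return(tx)
      hit <- runif(length(ch)) < rate
      if (any(hit)) {
        repl <- OCR_CONFUSION[ch[hit]]
        fallback <- ifelse(ch[hit] == "□", "■", "□")
        repl[is.na(repl)] <- fallback[is.na(repl)]
        ch[hit] <- repl
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Corrupt every message of a corpus with OCR-style noise
#'
#' Applies [inject_ocr_noise()] message by message with per-message seeds
#' derived from `seed` and the message index, so corpora corrupted at
#' different rates from the same seed have nested corruption sets.
#'
#' @param corpus Chat corpus data frame.
#' @param rate Per-character corruption probability.
#' @param seed Integer seed.
#' @return The corpus with corrupted `text`.
#' @export
corrupt_corpus <- function(corpus, rate, seed = 1L) {
  if (nrow(corpus) == 0 || rate == 0) return(corpus)
  corpus$text <- vapply(seq_len(nrow(corpus)), function(j) {
    inject_ocr_noise(corpus$text[j], rate, derive_seed(seed, j))
  }, character(1))
  corpus
}
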