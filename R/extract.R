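# Symptom mention detection, identity resolution, time-window assignment
# and construction of the patient x concept x window presence matrix.

SENTENCE_PUNCT <- c("。", "！", "？", "；", "，",
                    ".", "!", "?", ";", ",")

#' Detect symptom mentions in message texts
#'
#' For each concept, surface terms are matched as plain substrings
#' (Chinese has no whitespace tokens, so no word segmentation is applied),
#' longest term first, left to right; overlapping shorter matches of the
#' same concept are suppressed, while matches of different concepts may
#' overlap. Character offsets are 0-based, half-open.
#'
#' @param text A single message text.
#' @param lex A `perisym_compiled_lexicon`.
#' @return Data frame with columns `concept_id`, `start`, `end`,
#'   `matched_text` (possibly zero rows).
#' @examples
#' lex <- compile_lexicon(load_lexicon())
#' detect_mentions("月经量多还有血块", lex)
#' @export
detect_mentions <- function(text, lex) {
  stopifnot(inherits(lex, "perisym_compiled_lexicon"), length(text) == 1)
  out <- list()
  for (cc in names(lex$terms)) {
    taken <- matrix(numeric(0), ncol = 2)  # accepted [start, end) intervals
    rows <- list()
    for (term in lex$terms[[cc]]) {  # longest first
      hits <- gregexpr(term, text, fixed = TRUE)[[1]]
      if (hits[1] < 0) next
      len <- nchar(term)
      for (h in as.integer(hits)) {
        s <- h - 1L; e <- s + len
        overlaps <- nrow(taken) > 0 && any(s < taken[, 2] & e > taken[, 1])
        if (!overlaps) {
          taken <- rbind(taken, c(s, e))
          rows[[length(rows) + 1L]] <- c(s, e)
        }
      }
    }
    if (length(rows) > 0) {
      m <- do.call(rbind, rows)
      m <- m[order(m[, 1]), , drop = FALSE]
      out[[cc]] <- data.frame(
        concept_id = cc, start = as.integer(m[, 1]), end = as.integer(m[, 2]),
        matched_text = substring(text, m[, 1] + 1L, m[, 2]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(concept_id = character(), start = integer(),
                      end = integer(), matched_text = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the polarity of a detected mention
#'
#' A mention is negated iff a negation cue ends within `negation_window`
#' characters before the match start with no sentence punctuation
#' intervening between the cue and the term; otherwise it is affirmed.
#' Cues after the term never negate.
#'
#' @param text The message text.
#' @param start 0-based start offset of the mention.
#' @param lex A `perisym_compiled_lexicon` (supplies cues and window).
#' @return `"negated"` or `"affirmed"`.
#' @examples
#' lex <- compile_lexicon(load_lexicon())
#' classify_polarity("没有痛经", 2, lex)
#' @export
classify_polarity <- function(text, start, lex) {
  w <- lex$negation_window
  maxcue <- if (length(lex$negation_cues) > 0) max(nchar(lex$negation_cues)) else 0L
  lo <- max(0L, start - w - maxcue + 1L)  # cue may start before the window
  context <- substring(text, lo + 1L, start)  # characters [lo, start)
  for (cue in lex$negation_cues) {
    hits <- gregexpr(cue, context, fixed = TRUE)[[1]]
    if (hits[1] < 0) next
    for (h in as.integer(hits)) {
      cue_end <- lo + h - 1L + nchar(cue)       # 0-based, exclusive
      if (cue_end <= start - w) next            # ends too early
      between <- substring(text, cue_end + 1L, start)
      if (!any(vapply(SENTENCE_PUNCT, grepl, logical(1), x = between,
                      fixed = TRUE))) {
        return("negated")
      }
    }
  }
  "affirmed"
}

#' Assign a perioperative time window to a message date
#'
#' Offsets are whole days from the surgery date: negative offsets map to
#' `PREOP`, 1-30 to `M1`, 31-60 to `M2`, 61-90 to `M3`, 91-180 to `M4_6`.
#' The surgery day itself (offset 0) and offsets beyond 180 days are
#' unassigned (`NA`).
#'
#' @param message_date,surgery_date Dates (or ISO-8601 strings); vectorised.
#' @return Character vector of window labels or `NA`.
#' @export
assign_window <- function(message_date, surgery_date) {
  off <- as.integer(as.Date(message_date) - as.Date(surgery_date))
  window_of_offset(off)
}

window_of_offset <- function(off) {
  out <- rep(NA_character_, length(off))
  out[off < 0] <- "PREOP"
  out[off >= 1 & off <= 30] <- "M1"
  out[off >= 31 & off <= 60] <- "M2"
  out[off >= 61 & off <= 90] <- "M3"
  out[off >= 91 & off <= 180] <- "M4_6"
  out
}

#' Extract patient identities from a corpus
#'
#' Scans message texts for the self-introduction pattern (name plus
#' admission number) and records the announcing sender's alias. Exact
#' duplicate announcements are collapsed; conflicting names for one key are
#' reported and the first occurrence kept.
#'
#' @param corpus Chat corpus data frame.
#' @return Data frame `patient_key`, `name`, `alias` (one row per distinct
#'   key), with a data frame of conflicts in attribute `"conflicts"`.
#' @export
extract_identities <- function(corpus) {
  if (nrow(corpus) == 0) {
    return(structure(data.frame(patient_key = character(), name = character(),
                                alias = character(), stringsAsFactors = FALSE),
                     conflicts = data.frame()))
  }
  m <- regmatches(corpus$text, regexec(IDENTITY_PATTERN, corpus$text))
  hit <- lengths(m) == 3
  recs <- data.frame(
    patient_key = vapply(m[hit], `[`, character(1), 3),
    name = vapply(m[hit], `[`, character(1), 2),
    alias = corpus$sender_alias[hit],
    stringsAsFactors = FALSE
  )
  recs <- unique(recs)
  first <- !duplicated(recs$patient_key)
  conflicts <- recs[!first, , drop = FALSE]
  recs <- recs[first, , drop = FALSE]
  rownames(recs) <- NULL
  structure(recs, conflicts = conflicts)
}

#' Link chat identities to the EHR table
#'
#' Inner join on `patient_key`; identities without an EHR row and EHR rows
#' never seen in chat are reported separately.
#'
#' @param ids Identity records from [extract_identities()].
#' @param ehr EHR data frame with unique `patient_key`.
#' @return List with `cohort` (joined data frame), `unlinked_identities`,
#'   `unlinked_ehr` (character vectors of keys).
#' @export
link_to_ehr <- function(ids, ehr) {
  if (anyDuplicated(ehr$patient_key)) {
    stop_data("duplicate patient_key in EHR table")
  }
  linked_keys <- intersect(ids$patient_key, ehr$patient_key)
  cohort <- merge(ids, ehr, by = "patient_key",
                  suffixes = c("_chat", ""))
  cohort <- cohort[order(cohort$patient_key), , drop = FALSE]
  rownames(cohort) <- NULL
  list(cohort = cohort,
       unlinked_identities = setdiff(ids$patient_key, linked_keys),
       unlinked_ehr = setdiff(ehr$patient_key, linked_keys))
}

#' Detect, classify and time-stamp all mentions in a corpus
#'
#' Runs [detect_mentions()] and [classify_polarity()] over every message
#' (patient messages only by default), resolves each message's sender to a
#' patient via the identity records, and assigns day offsets and time
#' windows relative to the patient's surgery date.
#'
#' @param corpus Chat corpus data frame.
#' @param lex A `perisym_compiled_lexicon`.
#' @param cohort Linked cohort from [link_to_ehr()] (needs `patient_key`,
#'   `alias`, `surgery_date`). When `NULL`, mentions carry no patient,
#'   offset or window.
#' @param include_clinician Scan clinician messages too? Default `FALSE`.
#' @return Data frame of mentions: `message_id`, `sender_alias`,
#'   `patient_key`, `concept_id`, `start`, `end`, `matched_text`,
#'   `polarity`, `day_offset`, `window`.
#' @export
detect_corpus_mentions <- function(corpus, lex, cohort = NULL,
                                   include_clinician = FALSE) {
  scan <- corpus
  if (!include_clinician) {
    scan <- scan[scan$sender_role == "patient", , drop = FALSE]
  }
  rows <- vector("list", nrow(scan))
  for (j in seq_len(nrow(scan))) {
    mm <- detect_mentions(scan$text[j], lex)
    if (nrow(mm) == 0) next
    mm$polarity <- vapply(mm$start, function(s) {
      classify_polarity(scan$text[j], s, lex)
    }, character(1))
    mm$message_id <- scan$message_id[j]
    mm$sender_alias <- scan$sender_alias[j]
    mm$timestamp <- scan$timestamp[j]
    rows[[j]] <- mm
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    mentions <- data.frame(message_id = character(), sender_alias = character(),
                           patient_key = character(), concept_id = character(),
                           start = integer(), end = integer(),
                           matched_text = character(), polarity = character(),
                           day_offset = integer(), window = character(),
                           stringsAsFactors = FALSE)
    return(mentions)
  }
  mentions <- do.call(rbind, rows)
  if (!is.null(cohort) && nrow(cohort) > 0) {
    idx <- match(mentions$sender_alias, cohort$alias)
    mentions$patient_key <- cohort$patient_key[idx]
    sdate <- as.Date(cohort$surgery_date[idx])
    mentions$day_offset <- as.integer(as.Date(mentions$timestamp) - sdate)
    mentions$window <- window_of_offset(mentions$day_offset)
  } else {
    mentions$patient_key <- NA_character_
    mentions$day_offset <- NA_integer_
    mentions$window <- NA_character_
  }
  mentions$timestamp <- NULL
  mentions <- mentions[, c("message_id", "sender_alias", "patient_key",
                           "concept_id", "start", "end", "matched_text",
                           "polarity", "day_offset", "window")]
  rownames(mentions) <- NULL
  mentions
}

#' Build the patient x concept x window presence matrix
#'
#' A cell is present iff the patient has at least one affirmed mention of
#' the concept in the window; cells with only negated mentions are absent.
#' The grid covers every linked patient, every concept of the lexicon used
#' for extraction, and all five windows. Mentions that reference a patient
#' absent from the cohort are dropped with a warning.
#'
#' @param mentions Mention data frame from [detect_corpus_mentions()] (or
#'   a gold label set with columns `patient_key`, `concept_id`, `polarity`,
#'   `window`).
#' @param cohort Linked cohort (needs `patient_key`).
#' @param concepts Concepts defining the grid; defaults to those appearing
#'   in `mentions`, falling back to the shipped concept list.
#' @return Data frame `patient_key`, `concept_id`, `window`, `present`
#'   (class `perisym_presence`), with cohort size `N` as attribute `"N"`.
#' @export
build_presence_matrix <- function(mentions, cohort, concepts = NULL) {
  if (is.null(concepts)) {
    concepts <- unique(mentions$concept_id)
    if (length(concepts) == 0) concepts <- PERISYM_CONCEPTS
  }
  keys <- unique(cohort$patient_key)
  unknown <- !is.na(mentions$patient_key) &
    !(mentions$patient_key %in% keys)
  if (any(unknown)) {
    warning(sum(unknown), " mention(s) reference unknown patients; dropped")
  }
  mm <- mentions[!is.na(mentions$patient_key) & !unknown &
                   !is.na(mentions$window) &
                   mentions$polarity == "affirmed", , drop = FALSE]
  grid <- expand.grid(patient_key = keys, concept_id = concepts,
                      window = PERISYM_WINDOWS, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key <- function(p, c, w) paste(p, c, w, sep = "\r")
  present_cells <- unique(key(mm$patient_key, mm$concept_id, mm$window))
  grid$present <- key(grid$patient_key, grid$concept_id, grid$window) %in%
    present_cells
  grid <- grid[order(grid$patient_key, grid$concept_id,
                     match(grid$window, PERISYM_WINDOWS)), , drop = FALSE]
  rownames(grid) <- NULL
  structure(grid, N = length(keys), class = c("perisym_presence", "data.frame"))
}

#' Pre/post prevalence summary of a presence matrix
#'
#' Postoperative presence aggregates the four postoperative windows with a
#' logical OR, matching a single pre vs post comparison over the cohort.
#'
#' @param pm Presence matrix from [build_presence_matrix()].
#' @return Data frame `concept_id`, `n_pre`, `n_post`, `N`.
#' @export
presence_prepost <- function(pm) {
  N <- attr(pm, "N")
  concepts <- unique(pm$concept_id)
  pre <- pm[pm$window == "PREOP", , drop = FALSE]
  post <- pm[pm$window != "PREOP", , drop = FALSE]
  n_pre <- vapply(concepts, function(cc) {
    sum(pre$present[pre$concept_id == cc])
  }, 0L)
  post_any <- vapply(concepts, function(cc) {
    sub <- post[post$concept_id == cc, , drop = FALSE]
    sum(tapply(sub$present, sub$patient_key, any))
  }, 0)
  data.frame(concept_id = concepts, n_pre = as.integer(n_pre),
             n_post = as.integer(post_any),
             N = rep(N, length(concepts)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Median day of first postoperative report per concept
#'
#' For each concept, takes every patient's earliest affirmed postoperative
#' mention (day offset >= 1) and returns the median of those first-report
#' days. Concepts never affirmed after surgery get `NA`.
#'
#' @param mentions Mention data frame with `patient_key`, `concept_id`,
#'   `polarity`, `day_offset`.
#' @param cohort Linked cohort (restricts to linked patients).
#' @return Data frame `concept_id`, `n_patients`, `median_day`.
#' @export
first_report_times <- function(mentions, cohort) {
  mm <- mentions[!is.na(mentions$patient_key) &
                   mentions$patient_key %in% cohort$patient_key &
                   mentions$polarity == "affirmed" &
                   !is.na(mentions$day_offset) & mentions$day_offset >= 1 &
                   mentions$day_offset <= 180, , drop = FALSE]
  concepts <- unique(mentions$concept_id)
  res <- lapply(concepts, function(cc) {
    sub <- mm[mm$concept_id == cc, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(concept_id = cc, n_patients = 0L,
                        median_day = NA_real_, stringsAsFactors = FALSE))
    }
    firsts <- tapply(sub$day_offset, sub$patient_key, min)
    data.frame(concept_id = cc, n_patients = length(firsts),
               median_day = as.numeric(median(firsts)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
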