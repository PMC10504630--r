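# Reduction of raw chat text to fibroid-related, analysis-ready free text.

# Default inclusion keywords: fibroid vocabulary used to keep only senders
# whose conversations concern uterine fibroids.
DEFAULT_INCLUSION_KEYWORDS <- c("肌瘤", "子宫肌瘤", "多发子宫肌瘤", "多肌", "子肌")

# Low-analytical-value tokens stripped from message text.
DEFAULT_STOP_TOKENS <- c("早上", "下午", "上午", "晚上", "中午")

# Lines looking like pasted hospital examination records are dropped whole.
EXAM_RECORD_PATTERNS <- c(
  "检验报告", "检查报告", "报告单", "参考范围", "参考值",
  "白细胞", "红细胞", "血红蛋白", "血小板",
  "[0-9]+(\\.[0-9]+)?\\s*(×|x|X)\\s*10"
)

# URL bodies are restricted to ASCII URL characters so that CJK text glued
# to a link is not swallowed with it.
URL_PATTERN <- "(https?://|www\\.)[A-Za-z0-9./?#&=+_%:~-]*"

# Unicode emoji / pictograph / dingbat blocks plus variation selectors.
# (*UTF) forces PCRE into UTF mode even for all-ASCII subjects.
EMOJI_PATTERN <- paste0(
  "(*UTF)[\\x{1F000}-\\x{1FAFF}\\x{2600}-\\x{27BF}\\x{2B00}-\\x{2BFF}",
  "\\x{FE00}-\\x{FE0F}\\x{1F1E6}-\\x{1F1FF}\\x{2190}-\\x{21FF}",
  "\\x{2700}-\\x{27BF}]"
)

#' Cleaning configuration
#'
#' @param inclusion_keywords Non-empty character vector; a sender is kept
#'   iff at least one of their messages contains at least one keyword.
#' @param stop_tokens Literal tokens removed from message text.
#' @param train_fraction Fraction of patients assigned to the training
#'   split, strictly between 0 and 1.
#' @param seed Integer seed for the random split.
#' @return An object of class `perisym_cleaning_config`.
#' @export
cleaning_config <- function(inclusion_keywords = DEFAULT_INCLUSION_KEYWORDS,
                            stop_tokens = DEFAULT_STOP_TOKENS,
                            train_fraction = 0.30,
                            seed = 1L) {
  if (length(inclusion_keywords) == 0) {
    stop_config("inclusion_keywords must be non-empty")
  }
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_config("train_fraction must lie strictly between 0 and 1")
  }
  structure(list(inclusion_keywords = as.character(inclusion_keywords),
                 stop_tokens = as.character(stop_tokens),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "perisym_cleaning_config")
}

#' Keep only senders whose messages concern uterine fibroids
#'
#' Inclusion is decided at the sender level: a sender qualifies if any one
#' of their messages contains any inclusion keyword, and then all of their
#' messages are retained — symptom reports rarely repeat the word
#' "fibroid", so message-level filtering would discard most of the signal.
#'
#' @param corpus Chat corpus data frame.
#' @param config A [cleaning_config()].
#' @return The corpus restricted to qualifying senders.
#' @export
filter_fibroid_patients <- function(corpus, config = cleaning_config()) {
  if (length(config$inclusion_keywords) == 0) {
    stop_config("inclusion_keywords must be non-empty")
  }
  if (nrow(corpus) == 0) return(corpus)
  hit <- Reduce(`|`, lapply(config$inclusion_keywords, function(kw) {
    grepl(kw, corpus$text, fixed = TRUE)
  }))
  keep_senders <- unique(corpus$sender_alias[hit])
  corpus[corpus$sender_alias %in% keep_senders, , drop = FALSE]
}

#' Strip noise from a message text
#'
#' Removes, in order: pasted examination-record lines, URLs, emoji,
#' low-value stop tokens; then collapses whitespace runs (keeping the first
#' whitespace character of each run, so no character absent from the input
#' is ever introduced) and trims. Returns `NA_character_` when nothing
#' survives, signalling that the message should be dropped.
#'
#' @param text Character vector of message texts.
#' @param config A [cleaning_config()].
#' @return Character vector; `NA` for messages that became empty.
#' @examples
#' strip_noise("早上好\U0001F60A http://a.b/c 有点痛经")
#' @export
strip_noise <- function(text, config = cleaning_config()) {
  out <- vapply(text, function(tx) {
    lines <- strsplit(tx, "\n", fixed = TRUE)[[1]]
    if (length(lines) > 0) {
      is_exam <- Reduce(`|`, lapply(EXAM_RECORD_PATTERNS, function(p) {
        grepl(p, lines, perl = TRUE)
      }))
      lines <- lines[!is_exam]
    }
    tx <- paste(lines, collapse = "\n")
    tx <- gsub(URL_PATTERN, "", tx, perl = TRUE)
    tx <- gsub(EMOJI_PATTERN, "", tx, perl = TRUE)
    for (tok in config$stop_tokens) tx <- gsub(tok, "", tx, fixed = TRUE)
    tx <- gsub("(\\s)\\s+", "\\1", tx, perl = TRUE)
    tx <- gsub("^\\s+|\\s+$", "", tx, perl = TRUE)
    tx
  }, character(1), USE.NAMES = FALSE)
  out[!nzchar(out)] <- NA_character_
  out
}

#' Clean a corpus
#'
#' Applies [filter_fibroid_patients()] and [strip_noise()] and drops
#' messages that end up empty. Also returns per-class removal counts.
#'
#' @param corpus Chat corpus data frame.
#' @param config A [cleaning_config()].
#' @return List with `corpus` (cleaned) and `report` (data frame of counts:
#'   messages in, senders kept, messages after sender filter, messages
#'   dropped as empty, messages out).
#' @export
clean_corpus <- function(corpus, config = cleaning_config()) {
  n_in <- nrow(corpus)
  kept <- filter_fibroid_patients(corpus, config)
  cleaned <- kept
  cleaned$text <- strip_noise(kept$text, config)
  dropped_empty <- sum(is.na(cleaned$text))
  cleaned <- cleaned[!is.na(cleaned$text), , drop = FALSE]
  rownames(cleaned) <- NULL
  report <- data.frame(
    messages_in = n_in,
    senders_kept = length(unique(kept$sender_alias)),
    messages_after_sender_filter = nrow(kept),
    messages_dropped_empty = dropped_empty,
    messages_out = nrow(cleaned)
  )
  list(corpus = cleaned, report = report)
}

#' Split a corpus into training and validation portions by patient
#'
#' The partition is at the sender (patient) level so that no patient's
#' phrasing leaks between the lexicon-building and validation corpora. The
#' training split receives `round(train_fraction * n)` of the `n` patient
#' senders; clinician messages follow neither split and are excluded.
#'
#' @param corpus Chat corpus data frame.
#' @param train_fraction Fraction of patients assigned to training.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List with `train` and `validation` corpora.
#' @export
split_train_validation <- function(corpus, train_fraction = 0.30, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_config("train_fraction must lie strictly between 0 and 1")
  }
  pat <- corpus[corpus$sender_role == "patient", , drop = FALSE]
  senders <- sort(unique(pat$sender_alias))
  if (length(senders) < 2) {
    stop_data("corpus has fewer than 2 patients; cannot split")
  }
  n_train <- round(train_fraction * length(senders))
  n_train <- max(1L, min(length(senders) - 1L, n_train))
  train_senders <- with_seed(as.integer(seed), sample(senders, n_train))
  list(
    train = pat[pat$sender_alias %in% train_senders, , drop = FALSE],
    validation = pat[!pat$sender_alias %in% train_senders, , drop = FALSE]
  )
}
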