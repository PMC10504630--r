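#' @importFrom stats rnorm rpois rbinom runif median pchisq pnorm qnorm
#'   plogis binomial coef glm glm.fit setNames complete.cases
#' @importFrom utils read.delim write.csv read.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Perioperative time-window labels
#'
#' The five analysis windows anchored on the surgery date: the preoperative
#' period and postoperative months 1, 2, 3 and 4-6.
#'
#' @format Character vector of length 5.
#' @export
PERISYM_WINDOWS <- c("PREOP", "M1", "M2", "M3", "M4_6")

#' Symptom concept identifiers covered by the shipped lexicon
#'
#' @format Character vector of length 11.
#' @export
PERISYM_CONCEPTS <- c(
  "menorrhagia", "dysmenorrhea", "prolonged_menstrual_period",
  "menstrual_blood_clots", "dizziness", "fatigue", "lower_abdominal_pain",
  "menstrual_disorder", "vaginal_secretion", "intensified_dysmenorrhea",
  "frequent_urination"
)

# Deterministic 32-bit sub-seed derived from a base seed and a counter.
# Arithmetic in doubles to avoid integer overflow; result in [1, 2^31 - 2].
derive_seed <- function(seed, counter) {
  m <- 2147483629
  as.integer((abs(as.double(seed)) %% m * 48271 + as.double(counter) * 16807) %% m) + 1L
}

with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stop_config <- function(...) {
  stop(structure(class = c("perisym_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("perisym_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Read a chat corpus from JSONL
#'
#' One JSON object per line with fields `message_id`, `group_id`,
#' `sender_role`, `sender_alias`, `timestamp` (ISO-8601 date) and `text`.
#'
#' @param path Path to a JSONL file.
#' @return A data frame, one row per message.
#' @export
read_chat_jsonl <- function(path) {
  if (!file.exists(path)) stop_data("chat file not found: ", path)
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  as_chat_corpus(df)
}

#' Write a chat corpus to JSONL
#'
#' @param corpus Chat corpus data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chat_jsonl <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  jsonlite::stream_out(corpus, con, verbose = FALSE)
  invisible(path)
}

# Validate/canonicalise a chat corpus data frame.
as_chat_corpus <- function(df) {
  need <- c("message_id", "group_id", "sender_role", "sender_alias",
            "timestamp", "text")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_data("chat corpus missing fields: ", paste(miss, collapse = ", "))
  }
  df <- df[, need, drop = FALSE]
  for (v in need) df[[v]] <- as.character(df[[v]])
  rownames(df) <- NULL
  df
}

empty_chat_corpus <- function() {
  data.frame(message_id = character(), group_id = character(),
             sender_role = character(), sender_alias = character(),
             timestamp = character(), text = character(),
             stringsAsFactors = FALSE)
}

# CSV with "#"-prefixed metadata header lines (version, seed, input hashes).
write_csv_with_header <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(list(package = paste0("perisym ",
                                  as.character(utils::packageVersion("perisym")))),
            meta)
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_with_header <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
           encoding = "UTF-8")
}

# Character-wise helpers (all offsets 0-based, half-open).
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
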