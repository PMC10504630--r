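#' Load a symptom lexicon
#'
#' Reads a lexicon from TSV (columns `concept_id`, `surface_term`, `kind`,
#' optional `notes`) or from an equivalent JSON array of objects. Rows with
#' `kind = "term"` attach a surface form to a symptom concept; rows with
#' `kind = "negation_cue"` define the global negation cues and carry an
#' empty `concept_id`. The one-row-per-variant layout doubles as the
#' normalization mapping from surface variant to concept.
#'
#' Validation enforces the lexicon invariants: unique non-empty surface
#' terms, no term assigned to two concepts, known `kind` values. Violations
#' raise an error naming the offending row.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` lexicon file. Defaults to
#'   the lexicon shipped with the package.
#' @return A data frame of class `perisym_lexicon` with columns
#'   `concept_id`, `surface_term`, `kind`, `notes`.
#' @examples
#' lex <- load_lexicon()
#' table(lex$kind)
#' @export
load_lexicon <- function(path = system.file("extdata", "symptom_lexicon_zh.tsv",
                                            package = "perisym")) {
  if (!file.exists(path)) stop_config("lexicon file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                     quote = "", fill = TRUE)
  }
  if (nrow(df) == 0) {
    warning("empty lexicon file: ", path)
    df <- data.frame(concept_id = character(), surface_term = character(),
                     kind = character(), notes = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("perisym_lexicon", class(df))
    return(df)
  }
  if (!all(c("concept_id", "surface_term", "kind") %in% names(df))) {
    stop_config("lexicon must have columns concept_id, surface_term, kind")
  }
  if (is.null(df$notes)) df$notes <- ""
  df <- df[, c("concept_id", "surface_term", "kind", "notes")]
  for (v in names(df)) df[[v]] <- trimws(as.character(df[[v]]))
  df$notes[is.na(df$notes)] <- ""

  bad_kind <- which(!df$kind %in% c("term", "negation_cue"))
  if (length(bad_kind) > 0) {
    stop_config("row ", bad_kind[1], ": unknown kind '", df$kind[bad_kind[1]], "'")
  }
  empty <- which(df$surface_term == "" | is.na(df$surface_term))
  if (length(empty) > 0) stop_config("row ", empty[1], ": empty surface term")

  terms <- df[df$kind == "term", ]
  noconc <- which(df$kind == "term" & (df$concept_id == "" | is.na(df$concept_id)))
  if (length(noconc) > 0) stop_config("row ", noconc[1], ": term without concept_id")
  dup <- terms$surface_term[duplicated(terms$surface_term)]
  if (length(dup) > 0) {
    rows <- which(df$surface_term == dup[1] & df$kind == "term")
    stop_config("surface term '", dup[1], "' assigned more than once (rows ",
                paste(rows, collapse = ", "), ")")
  }
  class(df) <- c("perisym_lexicon", class(df))
  df
}

#' Compile a lexicon into matchers
#'
#' Orders each concept's surface terms longest-first (so the most specific
#' variant wins at a given position) and bundles the global negation cues
#' and the negation look-back window. The compiled object is treated as
#' immutable by all downstream matching.
#'
#' @param entries Lexicon data frame as returned by [load_lexicon()], or any
#'   data frame with columns `concept_id`, `surface_term`, `kind`.
#' @param negation_cues Character vector of negation cues; defaults to the
#'   `negation_cue` rows of `entries`.
#' @param negation_window Number of characters before a matched term within
#'   which a negation cue must end to flip the polarity to negated. Must be
#'   at least 1. The window never crosses sentence punctuation.
#' @return An object of class `perisym_compiled_lexicon`: a list with
#'   `terms` (named list concept -> character vector, longest first),
#'   `negation_cues`, and `negation_window`.
#' @examples
#' lex <- compile_lexicon(load_lexicon())
#' head(lex$terms$menorrhagia)
#' @export
compile_lexicon <- function(entries,
                            negation_cues = NULL,
                            negation_window = 6L) {
  if (negation_window < 1) stop_config("negation_window must be >= 1")
  terms <- entries[entries$kind == "term", , drop = FALSE]
  if (is.null(negation_cues)) {
    negation_cues <- entries$surface_term[entries$kind == "negation_cue"]
  }
  concepts <- unique(terms$concept_id)
  matchers <- lapply(concepts, function(cc) {
    tt <- terms$surface_term[terms$concept_id == cc]
    tt[order(-nchar(tt), tt)]
  })
  names(matchers) <- concepts
  structure(
    list(terms = matchers,
         negation_cues = as.character(negation_cues),
         negation_window = as.integer(negation_window)),
    class = "perisym_compiled_lexicon"
  )
}

#' @export
print.perisym_compiled_lexicon <- function(x, ...) {
  cat("Compiled symptom lexicon:", length(x$terms), "concepts,",
      sum(lengths(x$terms)), "surface terms,",
      length(x$negation_cues), "negation cues",
      sprintf("(negation window %d chars)\n", x$negation_window))
  invisible(x)
}

#' Prune a lexicon against a training corpus
#'
#' Counts, for every surface term, the number of (possibly overlapping)
#' occurrences in the training corpus and removes terms that are never
#' seen. Concepts whose entire term set is pruned are reported in the
#' returned report rather than silently dropped.
#'
#' @param compiled A `perisym_compiled_lexicon`.
#' @param train Cleaned chat corpus used for counting.
#' @return A list with `lexicon` (a pruned `perisym_compiled_lexicon`),
#'   `report` (data frame `term`, `concept`, `train_count`, `kept`), and
#'   `empty_concepts` (concepts left with no terms).
#' @export
prune_lexicon <- function(compiled, train) {
  stopifnot(inherits(compiled, "perisym_compiled_lexicon"))
  texts <- train$text %||% character()
  rows <- list()
  kept_terms <- list()
  for (cc in names(compiled$terms)) {
    tt <- compiled$terms[[cc]]
    counts <- vapply(tt, function(term) count_occurrences(texts, term), 0L)
    rows[[cc]] <- data.frame(term = tt, concept = cc,
                             train_count = as.integer(counts),
                             kept = counts > 0L,
                             stringsAsFactors = FALSE)
    kept_terms[[cc]] <- tt[counts > 0L]
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(report)) {
    report <- data.frame(term = character(), concept = character(),
                         train_count = integer(), kept = logical())
  }
  empty <- names(kept_terms)[lengths(kept_terms) == 0L]
  kept_terms <- kept_terms[lengths(kept_terms) > 0L]
  pruned <- structure(
    list(terms = kept_terms,
         negation_cues = compiled$negation_cues,
         negation_window = compiled$negation_window),
    class = "perisym_compiled_lexicon"
  )
  list(lexicon = pruned, report = report, empty_concepts = empty)
}

# Total number of occurrences of a fixed substring across texts (counting
# overlapping occurrences, stepping one character at a time).
count_occurrences <- function(texts, term) {
  if (length(texts) == 0) return(0L)
  n <- 0L
  for (tx in texts) {
    from <- 1L
    repeat {
      hit <- regexpr(term, substring(tx, from), fixed = TRUE)
      if (hit < 0) break
      n <- n + 1L
      from <- from + hit  # advance one past the match start: overlap-friendly
    }
  }
  n
}
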