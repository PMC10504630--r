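# End-to-end orchestration: simulate, clean, extract, evaluate, analyze.

#' Simulate a synthetic chat/EHR study and write its artifacts
#'
#' Wraps [generate_cohort()] and [generate_chat()] and writes
#' `chat.jsonl`, `gold.jsonl`, `ehr.csv` and a `run_info.json` sidecar
#' (package version, seed, output hashes) to `outdir`.
#'
#' @param config A [cohort_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the written paths and the generated
#'   objects (`cohort`, `corpus`, `gold`).
#' @export
run_simulate <- function(config = cohort_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  chat <- generate_chat(cohort, config)
  paths <- list(chat = file.path(outdir, "chat.jsonl"),
                gold = file.path(outdir, "gold.jsonl"),
                ehr = file.path(outdir, "ehr.csv"))
  write_chat_jsonl(chat$corpus, paths$chat)
  con <- file(paths$gold, open = "wb")
  jsonlite::stream_out(chat$gold, con, verbose = FALSE)
  close(con)
  write_csv_with_header(as.data.frame(cohort), paths$ehr,
                        meta = list(seed = config$seed,
                                    n_patients = config$n_patients))
  info <- list(package = "perisym",
               version = as.character(utils::packageVersion("perisym")),
               seed = config$seed,
               n_patients = config$n_patients,
               hashes = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(info, file.path(outdir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, list(cohort = cohort, corpus = chat$corpus,
                          gold = chat$gold)))
}

read_if_path <- function(x, reader) if (is.character(x) && length(x) == 1) reader(x) else x

#' Run the full extraction and analysis pipeline
#'
#' Stages: clean (sender-level fibroid filter + noise stripping), lexicon
#' (compile the shipped or supplied lexicon; prune against the training
#' split), extract (mentions, polarity, identity linkage, windows,
#' presence matrix), evaluate (kappa vs gold labels, when given) and
#' analyze (pre/post chi-square table, per-concept GEE trends, piecewise
#' trends, risk-factor screens, first-report medians). Each stage logs a
#' machine-readable count line; artifacts are written to `outdir` when it
#' is non-`NULL`.
#'
#' @param chat Chat corpus data frame or path to JSONL.
#' @param ehr EHR data frame or path to CSV (possibly with `#` headers).
#' @param lexicon Lexicon data frame or path; default the shipped lexicon.
#' @param gold Optional gold label data frame or JSONL path.
#' @param outdir Optional output directory.
#' @param seed Seed for the train/validation split.
#' @param train_fraction Fraction of patients in the lexicon-training split.
#' @param include_clinician Scan clinician messages for mentions?
#' @param prune Prune lexicon terms unseen in the training split?
#' @param quiet Suppress stage log lines?
#' @return List with `cleaning`, `lexicon`, `prune_report`, `identities`,
#'   `cohort`, `mentions`, `presence`, `prepost`, `table2`, `trends`,
#'   `piecewise`, `risk_screen`, `postop_screen`, `first_reports`, and
#'   (when gold is given) `kappa` and `discordances`.
#' @export
run_pipeline <- function(chat, ehr, lexicon = NULL, gold = NULL,
                         outdir = NULL, seed = 1L, train_fraction = 0.30,
                         include_clinician = FALSE, prune = TRUE,
                         quiet = FALSE) {
  log_line <- function(stage, ...) {
    if (!quiet) message(sprintf("[perisym] %s: %s", stage,
                                paste(..., collapse = " ")))
  }
  corpus <- as_chat_corpus(read_if_path(chat, read_chat_jsonl))
  ehr <- read_if_path(ehr, read_csv_with_header)
  gold <- read_if_path(gold, function(p) {
    jsonlite::stream_in(file(p), verbose = FALSE)
  })
  entries <- if (is.null(lexicon)) load_lexicon() else
    read_if_path(lexicon, load_lexicon)

  # clean ---------------------------------------------------------------
  cc <- cleaning_config(seed = seed, train_fraction = train_fraction)
  cleaned <- clean_corpus(corpus, cc)
  log_line("clean", "messages", cleaned$report$messages_in, "->",
           cleaned$report$messages_out)

  # lexicon -------------------------------------------------------------
  lex <- compile_lexicon(entries)
  prune_report <- NULL
  if (prune && nrow(cleaned$corpus) > 0 &&
      length(unique(cleaned$corpus$sender_alias[
        cleaned$corpus$sender_role == "patient"])) >= 2) {
    splits <- split_train_validation(cleaned$corpus, train_fraction, seed)
    pruned <- prune_lexicon(lex, splits$train)
    prune_report <- pruned$report
    # terms unseen in training are removed, but the full (unpruned)
    # lexicon is kept for extraction when pruning empties a concept
    if (length(pruned$lexicon$terms) > 0) lex_used <- pruned$lexicon
    else lex_used <- lex
  } else {
    lex_used <- lex
  }
  log_line("lexicon", length(lex_used$terms), "concepts,",
           sum(lengths(lex_used$terms)), "terms after pruning")

  # extract -------------------------------------------------------------
  ids <- extract_identities(cleaned$corpus)
  linked <- link_to_ehr(ids, ehr)
  mentions <- detect_corpus_mentions(cleaned$corpus, lex_used, linked$cohort,
                                     include_clinician = include_clinician)
  pm <- build_presence_matrix(mentions, linked$cohort,
                              concepts = names(lex$terms))
  prepost <- presence_prepost(pm)
  log_line("extract", nrow(mentions), "mentions,",
           nrow(linked$cohort), "patients linked")

  out <- list(cleaning = cleaned$report, lexicon = lex_used,
              prune_report = prune_report, identities = ids,
              cohort = linked$cohort, unlinked = linked[-1],
              mentions = mentions, presence = pm, prepost = prepost)

  # evaluate ------------------------------------------------------------
  if (!is.null(gold) && nrow(gold) > 0) {
    gold_pm <- build_presence_matrix(gold, linked$cohort,
                                     concepts = names(lex$terms))
    out$kappa <- kappa_presence(gold_pm, pm)
    out$discordances <- list_discordances(gold_pm, pm, mentions,
                                          cleaned$corpus)
    log_line("evaluate", sprintf("kappa = %.4f (%s), %d discordances",
                                 out$kappa$kappa, out$kappa$band,
                                 nrow(out$discordances)))
  }

  # analyze -------------------------------------------------------------
  if (nrow(pm) > 0 && nrow(linked$cohort) > 0) {
    out$table2 <- prepost_chi2_table(
      prepost[prepost$n_pre + prepost$n_post > 0, , drop = FALSE])
    out$trends <- fit_concept_trends(pm)
    out$piecewise <- fit_concept_piecewise(pm)
    preop_dys <- pm$present[pm$window == "PREOP" &
                              pm$concept_id == "dysmenorrhea"]
    names(preop_dys) <- pm$patient_key[pm$window == "PREOP" &
                                         pm$concept_id == "dysmenorrhea"]
    ord <- match(linked$cohort$patient_key, names(preop_dys))
    if ("dysmenorrhea" %in% pm$concept_id && any(preop_dys) &&
        !all(preop_dys)) {
      out$risk_screen <- risk_factor_screen(linked$cohort, preop_dys[ord])
      out$postop_screen <- postop_gee_screen(pm, linked$cohort)
    }
    out$first_reports <- first_report_times(mentions, linked$cohort)
    log_line("analyze", nrow(out$table2 %||% data.frame()),
             "concepts in pre/post table")
  }

  if (!is.null(outdir)) write_pipeline_outputs(out, outdir, seed)
  out
}

# Per-concept linear GEE trends over the five windows.
fit_concept_trends <- function(pm) {
  rows <- list()
  for (cc in unique(pm$concept_id)) {
    sub <- pm[pm$concept_id == cc, , drop = FALSE]
    if (length(unique(sub$present)) < 2) next
    fit <- tryCatch(gee_trend(sub), error = function(e) NULL)
    if (is.null(fit)) next
    rows[[cc]] <- data.frame(
      concept_id = cc, estimate_time = unname(fit$coefficients["time"]),
      se = unname(fit$robust_se["time"]), p = unname(fit$p["time"]),
      alpha = fit$alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fit_concept_piecewise <- function(pm) {
  rows <- list()
  for (cc in unique(pm$concept_id)) {
    sub <- pm[pm$concept_id == cc, , drop = FALSE]
    if (length(unique(sub$present)) < 2) next
    fit <- tryCatch(piecewise_trend(sub), error = function(e) NULL)
    if (is.null(fit)) next
    rows[[cc]] <- data.frame(
      concept_id = cc,
      seg1_estimate = unname(fit$segment1$coefficients["time"]),
      seg1_se = unname(fit$segment1$robust_se["time"]),
      seg1_p = unname(fit$segment1$p["time"]),
      seg2_estimate = unname(fit$segment2$coefficients["time"]),
      seg2_se = unname(fit$segment2$robust_se["time"]),
      seg2_p = unname(fit$segment2$p["time"]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(out, outdir, seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = seed)
  w <- function(df, name) {
    if (!is.null(df) && is.data.frame(df)) {
      write_csv_with_header(df, file.path(outdir, name), meta)
    }
  }
  w(out$cleaning, "cleaning_report.csv")
  w(out$prune_report, "prune_report.csv")
  w(as.data.frame(out$presence), "presence.csv")
  w(out$mentions, "mentions.csv")
  w(out$table2, "table2.csv")
  w(out$trends, "table3.csv")
  w(out$piecewise, "piecewise.csv")
  w(out$risk_screen, "table5.csv")
  w(out$postop_screen, "table6.csv")
  w(out$first_reports, "first_reports.csv")
  w(out$discordances, "discordances.csv")
  if (!is.null(out$kappa)) {
    w(data.frame(kappa = out$kappa$kappa, p_o = out$kappa$p_o,
                 p_e = out$kappa$p_e, n = out$kappa$n,
                 band = out$kappa$band), "kappa.csv")
  }
  invisible(outdir)
}
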