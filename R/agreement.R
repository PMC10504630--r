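# Agreement between automated extraction and gold annotations.

#' Cohen's kappa for two binary label sets
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed agreement and p_e the expected agreement from the marginal
#' products. The unit of agreement is whatever pairing the caller supplies;
#' in this pipeline it is the patient-window-concept presence decision.
#' Band cutpoints: <=0.20 poor, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 good, 0.81-1.00 excellent.
#'
#' @param gold,predicted Logical (or 2-level) vectors of equal length,
#'   aligned unit by unit.
#' @return List of class `perisym_kappa`: `kappa`, `p_o`, `p_e`, `n`,
#'   `band`, `table` (the 2x2 confusion matrix).
#' @examples
#' cohen_kappa(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, FALSE))
#' @export
cohen_kappa <- function(gold, predicted) {
  if (length(gold) != length(predicted)) {
    stop_data("label sets must align: lengths ", length(gold), " vs ",
              length(predicted))
  }
  g <- as.logical(gold); p <- as.logical(predicted)
  if (any(is.na(g)) || any(is.na(p))) stop_data("labels must not be NA")
  n <- length(g)
  if (n == 0) stop_data("empty label sets")
  tab <- matrix(c(sum(g & p), sum(g & !p), sum(!g & p), sum(!g & !p)),
                nrow = 2, byrow = TRUE,
                dimnames = list(gold = c("present", "absent"),
                                predicted = c("present", "absent")))
  p_o <- (tab[1, 1] + tab[2, 2]) / n
  p_e <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  if (p_e >= 1) {
    stop_data("kappa undefined: both raters are constant (p_e = 1); ",
              "gold all ", if (all(g)) "present" else "absent",
              ", predicted all ", if (all(p)) "present" else "absent")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n = n,
                 band = kappa_band(kappa), table = tab),
            class = "perisym_kappa")
}

#' @export
print.perisym_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (%s); p_o = %.4f, p_e = %.4f, n = %d\n",
              x$kappa, x$band, x$p_o, x$p_e, x$n))
  invisible(x)
}

#' Interpretation band for a kappa value
#'
#' @param kappa Numeric in \[-1, 1\].
#' @return One of `"poor"`, `"fair"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
kappa_band <- function(kappa) {
  vapply(kappa, function(k) {
    if (k <= 0.20) "poor"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "good"
    else "excellent"
  }, character(1))
}

#' Kappa between two presence matrices
#'
#' Aligns two presence matrices on (patient, concept, window) cells and
#' computes [cohen_kappa()] over the shared grid.
#'
#' @param gold_pm,pred_pm Presence matrices from [build_presence_matrix()].
#' @return A `perisym_kappa`.
#' @export
kappa_presence <- function(gold_pm, pred_pm) {
  key <- function(pm) paste(pm$patient_key, pm$concept_id, pm$window,
                            sep = "\r")
  kg <- key(gold_pm); kp <- key(pred_pm)
  common <- intersect(kg, kp)
  if (length(common) == 0) stop_data("presence matrices share no cells")
  cohen_kappa(gold_pm$present[match(common, kg)],
              pred_pm$present[match(common, kp)])
}

#' List disagreeing cells between gold and predicted labels
#'
#' Every (unit, concept) pair on which the two label sets disagree, with
#' both labels and, when a corpus and mention set are supplied, a source
#' text snippet for adjudication.
#'
#' @param gold_pm,pred_pm Presence matrices (or any data frames with
#'   `patient_key`, `concept_id`, `window`, `present`).
#' @param mentions Optional mention data frame used to locate a snippet.
#' @param corpus Optional corpus for snippet text.
#' @return Data frame `patient_key`, `concept_id`, `window`, `gold`,
#'   `predicted`, `snippet`.
#' @export
list_discordances <- function(gold_pm, pred_pm, mentions = NULL,
                              corpus = NULL) {
  key <- function(pm) paste(pm$patient_key, pm$concept_id, pm$window,
                            sep = "\r")
  kg <- key(gold_pm); kp <- key(pred_pm)
  common <- intersect(kg, kp)
  gi <- match(common, kg); pi <- match(common, kp)
  dis <- which(gold_pm$present[gi] != pred_pm$present[pi])
  out <- data.frame(
    patient_key = gold_pm$patient_key[gi][dis],
    concept_id = gold_pm$concept_id[gi][dis],
    window = gold_pm$window[gi][dis],
    gold = gold_pm$present[gi][dis],
    predicted = pred_pm$present[pi][dis],
    snippet = rep(NA_character_, length(dis)),
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0 && !is.null(mentions) && !is.null(corpus)) {
    for (r in seq_len(nrow(out))) {
      hit <- mentions$patient_key == out$patient_key[r] &
        mentions$concept_id == out$concept_id[r] &
        !is.na(mentions$window) & mentions$window == out$window[r]
      if (any(hit, na.rm = TRUE)) {
        mid <- mentions$message_id[which(hit)[1]]
        out$snippet[r] <- corpus$text[match(mid, corpus$message_id)]
      }
    }
  }
  rownames(out) <- NULL
  out
}
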