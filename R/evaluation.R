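check_same_ids <- function(a, b) {
  extra_a <- setdiff(a, b)
  extra_b <- setdiff(b, a)
  if (length(extra_a) || length(extra_b)) {
    abort_validation(sprintf(
      "doc_id sets differ; only in first: [%s]; only in second: [%s]",
      paste(extra_a, collapse = ", "), paste(extra_b, collapse = ", ")))
  }
}

#' Confusion matrix with relevant (class 0) as the positive class
#'
#' @param pred,gold Data frames with `doc_id` and `label` over identical id
#'   sets; order is irrelevant.
#' @return Object of class `amr_confusion` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(pred, gold) {
  check_doc_ids(pred$doc_id)
  check_doc_ids(gold$doc_id)
  check_same_ids(pred$doc_id, gold$doc_id)
  p <- pred$label[match(gold$doc_id, pred$doc_id)]
  g <- gold$label
  structure(
    list(tp = sum(p == 0L & g == 0L), fp = sum(p == 0L & g == 1L),
         fn = sum(p == 1L & g == 0L), tn = sum(p == 1L & g == 1L)),
    class = "amr_confusion"
  )
}

#' Assemble a confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative counts (class 0 = relevant is positive).
#' @return Object of class `amr_confusion`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort_validation("confusion counts must be non-negative integers")
  }
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "amr_confusion")
}

#' @export
print.amr_confusion <- function(x, ...) {
  cat("<amr_confusion> (positive class = 0, relevant)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("gold 0", "gold 1"), c("pred 0", "pred 1")))
  print(m)
  invisible(x)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Per-class precision, recall, F1 and accuracy from a confusion matrix
#'
#' Class 0 (relevant) is the positive class; class-1 metrics swap the roles
#' of tp/tn and fp/fn. F1 is the harmonic mean of precision and recall. A
#' zero denominator yields 0 and is listed in `flags`. Values are reported
#' at full precision alongside a 2-decimal half-up rounding (`rounded`).
#'
#' @param cm An `amr_confusion`.
#' @return Object of class `amr_metrics`: per class `precision`, `recall`,
#'   `f1`, `support`, plus `accuracy`, `rounded`, and `flags`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "amr_confusion"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) abort_validation("empty confusion matrix")
  flags <- character()
  note <- function(den, what) {
    if (den == 0) flags <<- c(flags, what)
    den
  }
  m <- list(
    precision_0 = safe_div(cm$tp, note(cm$tp + cm$fp, "precision_0")),
    recall_0    = safe_div(cm$tp, note(cm$tp + cm$fn, "recall_0")),
    precision_1 = safe_div(cm$tn, note(cm$tn + cm$fn, "precision_1")),
    recall_1    = safe_div(cm$tn, note(cm$tn + cm$fp, "recall_1")),
    support_0   = cm$tp + cm$fn,
    support_1   = cm$tn + cm$fp,
    accuracy    = (cm$tp + cm$tn) / total
  )
  hmean <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  m$f1_0 <- hmean(m$precision_0, m$recall_0)
  m$f1_1 <- hmean(m$precision_1, m$recall_1)
  keys <- c("precision_0", "recall_0", "f1_0", "precision_1", "recall_1",
            "f1_1", "accuracy")
  m$rounded <- lapply(setNames(keys, keys),
                      function(k) round_half_up(m[[k]], 2))
  m$flags <- flags
  m$confusion <- cm
  structure(m, class = "amr_metrics")
}

#' @export
print.amr_metrics <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Format a metrics report as a per-class text table
#'
#' @param x An `amr_metrics`.
#' @param ... Unused.
#' @return Character vector of report lines.
#' @export
format.amr_metrics <- function(x, ...) {
  r <- x$rounded
  c(sprintf("%-6s %-10s %-7s %-9s %-8s %s",
            "Class", "Precision", "Recall", "F1-score", "Support", "Accuracy"),
    sprintf("%-6d %-10.2f %-7.2f %-9.2f %-8d %.2f",
            0L, r$precision_0, r$recall_0, r$f1_0, x$support_0, r$accuracy),
    sprintf("%-6d %-10.2f %-7.2f %-9.2f %-8d",
            1L, r$precision_1, r$recall_1, r$f1_1, x$support_1))
}

#' Agreement between automatic and gold labels
#'
#' Counts exact label agreements overall and within each gold class, and
#' reports percentages both at full precision and rounded half-up to the
#' nearest integer.
#'
#' @param auto Data frame with `doc_id`, `label` (automatic labels).
#' @param gold Data frame with `doc_id`, `label` (expert labels), same ids.
#' @return Object of class `amr_agreement`: `n_agree`, `total`,
#'   `pct_overall`, `pct_relevant`, `pct_irrelevant`, and `rounded`.
#' @export
label_agreement <- function(auto, gold) {
  check_doc_ids(auto$doc_id)
  check_doc_ids(gold$doc_id)
  check_same_ids(auto$doc_id, gold$doc_id)
  a <- auto$label[match(gold$doc_id, auto$doc_id)]
  g <- gold$label
  agree <- a == g
  pct <- function(num, den) if (den == 0) 0 else 100 * num / den
  out <- list(
    n_agree = sum(agree), total = length(g),
    pct_overall = pct(sum(agree), length(g)),
    pct_relevant = pct(sum(agree & g == 0L), sum(g == 0L)),
    pct_irrelevant = pct(sum(agree & g == 1L), sum(g == 1L))
  )
  out$rounded <- lapply(out[c("pct_overall", "pct_relevant", "pct_irrelevant")],
                        round_half_up)
  structure(out, class = "amr_agreement")
}

#' @export
print.amr_agreement <- function(x, ...) {
  cat(sprintf(
    "<amr_agreement> %d/%d agree (%d%% overall; relevant %d%%, irrelevant %d%%)\n",
    x$n_agree, x$total, x$rounded$pct_overall, x$rounded$pct_relevant,
    x$rounded$pct_irrelevant))
  invisible(x)
}

metrics_as_list <- function(m) {
  keep <- c("precision_0", "recall_0", "f1_0", "precision_1", "recall_1",
            "f1_1", "support_0", "support_1", "accuracy")
  c(m[keep],
    list(rounded = m$rounded, flags = m$flags,
         confusion = m$confusion[c("tp", "fp", "fn", "tn")]))
}

#' Write a machine-readable evaluation report
#'
#' JSON with all confusion counts and metrics (full precision and rounded),
#' plus optional labeling-agreement blocks, alongside a human-readable text
#' table.
#'
#' @param metrics An `amr_metrics`.
#' @param path Output path for the JSON report; a `.txt` sibling carries the
#'   text table.
#' @param agreement Optional named list of `amr_agreement` objects.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(metrics, path, agreement = NULL) {
  payload <- list(classifier = metrics_as_list(metrics))
  if (!is.null(agreement)) {
    payload$agreement <- lapply(agreement, function(a) {
      a_list <- unclass(a)
      a_list
    })
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  writeLines(format(metrics), sub("\\.json$", ".txt", path))
  invisible(path)
}
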