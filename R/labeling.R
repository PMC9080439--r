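#' Weak labeling by arithmetic-mean thresholding
#'
#' The threshold is the arithmetic mean of all scores in the corpus; a
#' document is labeled relevant (class 0) when its score is equal to or
#' greater than the mean, irrelevant (class 1) otherwise. The mean is taken
#' over the entire scored corpus, including any documents later held out as
#' a gold test set (hold-out applies to classifier training only).
#'
#' @param scores Data frame `doc_id, method, score` from one scoring method.
#' @return A list with `summary` (mean score, class counts, method) and
#'   `labels` (data frame `doc_id, method, score, label`).
#' @export
mean_threshold_label <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) < 1L) {
    abort_validation("need at least one score")
  }
  if (length(unique(scores$method)) != 1L) {
    abort_validation("all scores must come from a single method")
  }
  check_doc_ids(scores$doc_id)
  threshold <- mean(scores$score)
  # ties at the mean are relevant; the epsilon keeps that rule stable under
  # floating-point summation noise (mean(c(.2,.4,.6)) > .4 in doubles)
  eps <- 1e-12 * max(1, abs(threshold))
  label <- ifelse(scores$score >= threshold - eps, 0L, 1L)
  labels <- data.frame(doc_id = scores$doc_id, method = scores$method,
                       score = scores$score, label = label,
                       stringsAsFactors = FALSE)
  summary <- list(mean_score = threshold,
                  n_relevant = sum(label == 0L),
                  n_irrelevant = sum(label == 1L),
                  method = scores$method[[1]])
  stopifnot(summary$n_relevant + summary$n_irrelevant == nrow(scores))
  list(summary = summary, labels = labels)
}
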