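mk_labels <- function(labels, ids = sprintf("G%03d", seq_along(labels))) {
  data.frame(doc_id = ids, label = as.integer(labels),
             stringsAsFactors = FALSE)
}

test_that("confusion counts follow the positive-class-0 convention", {
  gold <- mk_labels(rep(c(0, 1), c(4, 6)))
  cm <- confusion_matrix(gold, gold)
  expect_identical(cm[c("tp", "fp", "fn", "tn")],
                   list(tp = 4L, fp = 0L, fn = 0L, tn = 6L))

  flipped <- mk_labels(1L - gold$label, gold$doc_id)
  cmf <- confusion_matrix(flipped, gold)
  expect_identical(cmf$tp, 0L)
  expect_identical(cmf$tn, 0L)

  # 62-document gold set (15 relevant / 47 irrelevant) with one error on the
  # relevant class and five on the irrelevant class
  gold62 <- mk_labels(rep(c(0, 1), c(15, 47)))
  pred62 <- mk_labels(c(rep(0, 14), 1, rep(0, 5), rep(1, 42)), gold62$doc_id)
  cm62 <- confusion_matrix(pred62, gold62)
  expect_identical(cm62[c("tp", "fn", "fp", "tn")],
                   list(tp = 14L, fn = 1L, fp = 5L, tn = 42L))
  # order invariance
  perm <- withr::with_seed(1, sample(62))
  expect_identical(confusion_matrix(pred62[perm, ], gold62), cm62)
})

test_that("id mismatches are reported with the symmetric difference", {
  a <- mk_labels(c(0, 1), ids = c("A", "B"))
  b <- mk_labels(c(0, 1), ids = c("A", "C"))
  expect_error(confusion_matrix(a, b), "B.*C", class = "amrtriage_validation")
})

test_that("per-class metrics reproduce the reference confusion arithmetic", {
  m1 <- classification_metrics(confusion_counts(tp = 14, fp = 5, fn = 1, tn = 42))
  expect_identical(m1$rounded[c("precision_0", "recall_0", "f1_0", "f1_1",
                                "accuracy")],
                   list(precision_0 = 0.74, recall_0 = 0.93, f1_0 = 0.82,
                        f1_1 = 0.93, accuracy = 0.90))
  expect_identical(c(m1$support_0, m1$support_1), c(15L, 47L))

  m2 <- classification_metrics(confusion_counts(tp = 9, fp = 33, fn = 6, tn = 14))
  expect_identical(m2$rounded[c("precision_0", "recall_0", "f1_0", "accuracy")],
                   list(precision_0 = 0.21, recall_0 = 0.60, f1_0 = 0.32,
                        accuracy = 0.37))

  perfect <- classification_metrics(confusion_counts(10, 0, 0, 20))
  expect_true(all(unlist(perfect$rounded) == 1))

  # a zero denominator yields 0 and is flagged, never NaN
  deg <- classification_metrics(confusion_counts(0, 0, 5, 5))
  expect_identical(deg$precision_0, 0)
  expect_true("precision_0" %in% deg$flags)
  expect_error(classification_metrics(confusion_counts(0, 0, 0, 0)),
               class = "amrtriage_validation")
})

test_that("metrics agree with a brute-force recount on random labelings", {
  for (s in 1:10) {
    n <- withr::with_seed(s, sample(5:200, 1))
    gold <- mk_labels(withr::with_seed(s, sample(0:1, n, replace = TRUE)))
    pred <- mk_labels(withr::with_seed(s + 1000, sample(0:1, n, replace = TRUE)),
                      gold$doc_id)
    m <- classification_metrics(confusion_matrix(pred, gold))
    o <- oracle_metrics(pred, gold)
    for (k in c("precision_0", "recall_0", "f1_0", "precision_1", "recall_1",
                "f1_1", "accuracy")) {
      expect_equal(m[[k]], o[[k]], tolerance = 1e-12, label = k)
    }
    expect_identical(m$confusion[c("tp", "fp", "fn", "tn")],
                     lapply(o[c("tp", "fp", "fn", "tn")], as.integer))

    # swapping the class convention swaps the metric blocks exactly
    sw <- classification_metrics(
      confusion_matrix(mk_labels(1L - pred$label, pred$doc_id),
                       mk_labels(1L - gold$label, gold$doc_id)))
    expect_equal(sw$precision_0, m$precision_1)
    expect_equal(sw$recall_1, m$recall_0)
    expect_equal(sw$f1_0, m$f1_1)
    expect_equal(sw$accuracy, m$accuracy)

    # accuracy is the support-weighted mean of the two recalls
    expect_equal(m$accuracy,
                 (m$recall_0 * m$support_0 + m$recall_1 * m$support_1) /
                   (m$support_0 + m$support_1))
  }
})

test_that("agreement percentages follow the per-class decomposition", {
  gold <- mk_labels(rep(c(0, 1), c(15, 47)))
  # 12 of 15 relevant + 32 of 47 irrelevant agree: 44 of 62
  auto <- mk_labels(c(rep(0, 12), rep(1, 3), rep(0, 15), rep(1, 32)),
                    gold$doc_id)
  a <- label_agreement(auto, gold)
  expect_identical(a$n_agree, 44L)
  expect_identical(a$rounded$pct_overall, 71)
  expect_identical(a$rounded$pct_relevant, 80)
  expect_identical(a$rounded$pct_irrelevant, 68)

  # 10 + 16 agreements: 26 of 62
  auto2 <- mk_labels(c(rep(0, 10), rep(1, 5), rep(0, 31), rep(1, 16)),
                     gold$doc_id)
  a2 <- label_agreement(auto2, gold)
  expect_identical(a2$n_agree, 26L)
  expect_identical(a2$rounded$pct_overall, 42)
  expect_identical(a2$rounded$pct_irrelevant, 34)
  # 10/15 = 66.7%: rounds to 67 under half-up rounding
  expect_identical(a2$rounded$pct_relevant, 67)

  self <- label_agreement(gold, gold)
  expect_identical(unlist(self$rounded), c(pct_overall = 100,
                                           pct_relevant = 100,
                                           pct_irrelevant = 100))
})

test_that("evaluation reports serialize counts, metrics and agreement", {
  dir <- withr::local_tempdir()
  m <- classification_metrics(confusion_counts(14, 5, 1, 42))
  gold <- mk_labels(rep(c(0, 1), c(3, 3)))
  agr <- list(weak = label_agreement(gold, gold))
  p <- file.path(dir, "evaluation.json")
  write_evaluation(m, p, agreement = agr)
  back <- jsonlite::read_json(p)
  expect_equal(back$classifier$confusion$tp, 14)
  expect_equal(back$classifier$rounded$accuracy, 0.9)
  expect_equal(back$agreement$weak$n_agree, 6)
  expect_true(file.exists(file.path(dir, "evaluation.txt")))
  txt <- readLines(file.path(dir, "evaluation.txt"))
  expect_match(txt[1], "Precision")
})
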