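#' SVM training configuration
#'
#' RBF-kernel support-vector classification with hyperparameters chosen by
#' grid search over `C_grid` x `gamma_grid` under stratified k-fold
#' cross-validated accuracy. The default grids are a standard log grid
#' bracketing the RBF regimes; `NA` in `gamma_grid` stands for
#' `1 / n_features`, resolved at fit time.
#'
#' @param C_grid Positive margin-parameter candidates.
#' @param gamma_grid Positive RBF-width candidates (`NA` = 1/n_features).
#' @param folds Cross-validation folds (>= 2; default 5).
#' @param seed Integer seed for fold construction.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(C_grid = c(0.1, 1, 10, 100),
                       gamma_grid = c(1e-3, 1e-2, 1e-1, 1, NA),
                       folds = 5, seed = 1) {
  if (!length(C_grid) || !length(gamma_grid)) {
    abort_validation("C and gamma grids must be non-empty")
  }
  if (any(C_grid <= 0) || any(gamma_grid <= 0, na.rm = TRUE)) {
    abort_validation("C and gamma candidates must be positive")
  }
  if (!is_count(folds) || folds < 2) abort_validation("folds must be >= 2")
  structure(list(kernel = "radial", C_grid = sort(C_grid),
                 gamma_grid = gamma_grid, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' TF-IDF feature table for classification
#'
#' The classifier's attribute vector is the lexicon vocabulary weighted by
#' TF-IDF, identical to the bag-of-words scoring table ([tfidf_weights()]);
#' columns are fixed in lexicographic term order so training and prediction
#' always agree.
#'
#' @inheritParams tfidf_weights
#' @return Numeric matrix, documents x lexicon terms.
#' @export
featurize <- function(tokens, lexicon) {
  tfidf_weights(tokens, lexicon)
}

# Stratified fold ids: within each class, documents are shuffled with the
# seeded RNG and dealt round-robin into folds.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Train an RBF-SVM on weakly labeled TF-IDF features
#'
#' Excludes the gold test ids, grid-searches `C x gamma` by mean stratified
#' k-fold cross-validated accuracy (ties broken toward smaller C, then
#' smaller gamma), and refits the winning configuration on all remaining
#' training rows. Feature columns are never rescaled (TF-IDF weights are
#' already comparable and many columns are sparse).
#'
#' @param features Matrix from [featurize()] (rownames are doc ids).
#' @param labels Data frame with `doc_id` and `label` (the weak labels).
#' @param config An [svm_config()].
#' @param exclude_ids Doc ids (the expert-labeled test set) withheld from
#'   both the grid search and the final fit.
#' @return An object of class `amr_svm` with elements `fit`, `C`, `gamma`,
#'   `feature_terms`, `cv_score`, `train_ids`, `config`.
#' @export
train_svm <- function(features, labels, config = svm_config(),
                      exclude_ids = character()) {
  stopifnot(inherits(config, "svm_config"))
  lab <- setNames(labels$label, labels$doc_id)
  ids <- setdiff(rownames(features), exclude_ids)
  ids <- ids[ids %in% names(lab)]
  x <- features[ids, , drop = FALSE]
  y <- factor(lab[ids], levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2L) {
    abort_validation("training set has a single class after exclusions")
  }
  if (min(table(y)) < config$folds) {
    abort_validation(sprintf(
      "fold count %d exceeds minority-class size %d",
      config$folds, min(table(y))))
  }

  gamma_grid <- config$gamma_grid
  gamma_grid[is.na(gamma_grid)] <- 1 / ncol(x)
  gamma_grid <- sort(unique(gamma_grid))

  fold <- stratified_folds(as.integer(as.character(y)), config$folds,
                           config$seed)
  best <- list(acc = -Inf, C = NA_real_, gamma = NA_real_)
  for (C in config$C_grid) {          # ascending: first winner = smallest C
    for (g in gamma_grid) {           # then smallest gamma
      correct <- 0L
      for (k in seq_len(config$folds)) {
        tr <- fold != k
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = C, gamma = g, scale = FALSE)
        pred <- predict(fit, x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == y[!tr])
      }
      acc <- correct / length(y)
      if (acc > best$acc) best <- list(acc = acc, C = C, gamma = g)
    }
  }

  fit <- e1071::svm(x, y, kernel = "radial", cost = best$C,
                    gamma = best$gamma, scale = FALSE)
  structure(
    list(fit = fit, C = best$C, gamma = best$gamma,
         feature_terms = colnames(features), cv_score = best$acc,
         train_ids = ids, config = config, format_version = 1L),
    class = "amr_svm"
  )
}

#' @export
print.amr_svm <- function(x, ...) {
  cat(sprintf(
    "<amr_svm> RBF, C = %g, gamma = %g, CV accuracy = %.3f, %d features\n",
    x$C, x$gamma, x$cv_score, length(x$feature_terms)))
  invisible(x)
}

#' Predict relevance labels for documents
#'
#' @param object A trained [train_svm()] classifier.
#' @param features Feature matrix whose columns match the model's
#'   `feature_terms` exactly (order included).
#' @param ... Unused.
#' @return Data frame `doc_id, method, score, label` (method `"svm_rbf"`;
#'   score is the signed decision value, positive toward class 0).
#' @export
predict.amr_svm <- function(object, features, ...) {
  if (!identical(colnames(features), object$feature_terms)) {
    abort_validation("feature columns do not match the trained model")
  }
  pred <- predict(object$fit, features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1]
  data.frame(doc_id = rownames(features), method = "svm_rbf",
             score = unname(dv),
             label = as.integer(as.character(pred)),
             stringsAsFactors = FALSE)
}

#' Persist and restore a trained classifier
#'
#' The artifact is a single file carrying the fitted decision function, the
#' chosen hyperparameters, the feature term list and a format-version tag.
#'
#' @param model An `amr_svm`.
#' @param path File path.
#' @return `load_classifier()` returns the `amr_svm`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "amr_svm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "amr_svm") || is.null(model$format_version)) {
    abort_validation("not a classifier artifact")
  }
  model
}
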