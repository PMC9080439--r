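#' PV-DM embedding hyperparameters
#'
#' Defaults follow the standard configuration for distributed-memory
#' paragraph vectors on full-text biomedical corpora: 300-dimensional
#' vectors, initial learning rate 0.025 decaying linearly to 0.00025,
#' vocabulary pruned below 3 occurrences, 30 epochs, dm = 1 (distributed
#' memory). Window size and negative-sampling count are the common PV-DM
#' defaults (5 each). Training is single-threaded (`workers = 1`) so a fixed
#' seed gives bit-identical models.
#'
#' @param vector_size Embedding dimensionality (> 0).
#' @param window Context window half-width.
#' @param alpha,min_alpha Initial and final learning rate
#'   (0 < min_alpha <= alpha).
#' @param min_count Words with total corpus frequency below this are ignored.
#' @param epochs Training passes over the corpus (>= 1).
#' @param negative Noise words per positive example in negative sampling.
#' @param dm Training algorithm flag; only 1 (PV-DM) is supported.
#' @param workers Worker threads; only 1 is supported (determinism).
#' @param seed Integer seed for initialization and negative sampling.
#' @return An object of class `pvdm_params`.
#' @export
pvdm_params <- function(vector_size = 300, window = 5, alpha = 0.025,
                        min_alpha = 0.00025, min_count = 3, epochs = 30,
                        negative = 5, dm = 1, workers = 1, seed = 1) {
  if (!is_count(vector_size)) abort_validation("vector_size must be > 0")
  if (!(min_alpha > 0 && min_alpha <= alpha)) {
    abort_validation("need 0 < min_alpha <= alpha")
  }
  if (!is_count(epochs)) abort_validation("epochs must be >= 1")
  if (dm != 1) abort_validation("only dm = 1 (PV-DM) is supported")
  if (workers != 1) abort_validation("only workers = 1 is supported")
  structure(
    list(vector_size = as.integer(vector_size), window = as.integer(window),
         alpha = alpha, min_alpha = min_alpha,
         min_count = as.integer(min_count), epochs = as.integer(epochs),
         negative = as.integer(negative), dm = 1L, workers = 1L,
         seed = as.integer(seed)),
    class = "pvdm_params"
  )
}

#' Train a PV-DM paragraph-vector model
#'
#' Learns one dense vector per document jointly with word vectors, by
#' predicting each word from the mean of the paragraph vector and its
#' windowed context (negative sampling, linear learning-rate decay). The
#' vocabulary is pruned at `min_count` and ordered by decreasing frequency
#' (ties lexicographic) for determinism.
#'
#' @param tokens An `amr_tokens` corpus (>= 2 documents with tokens).
#' @param params A [pvdm_params()].
#' @return An object of class `pvdm_model`.
#' @export
train_pvdm <- function(tokens, params = pvdm_params()) {
  stopifnot(inherits(params, "pvdm_params"))
  docs <- lapply(tokens, `[[`, "tokens")
  docs <- docs[lengths(docs) > 0L]
  if (length(docs) < 2L) {
    abort_validation("PV-DM training needs at least 2 non-empty documents")
  }
  ids <- token_ids(tokens[lengths(lapply(tokens, `[[`, "tokens")) > 0L])
  check_doc_ids(ids)

  tab <- table(unlist(docs, use.names = FALSE))
  tab <- tab[tab >= params$min_count]
  if (!length(tab)) {
    abort_validation(sprintf(
      "vocabulary empty after min_count = %d pruning", params$min_count))
  }
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  vocab <- names(tab)[ord]
  counts <- as.integer(tab)[ord]
  lookup <- setNames(seq_along(vocab), vocab)

  indexed <- lapply(docs, function(tk) {
    idx <- lookup[tk]
    as.integer(idx[!is.na(idx)]) - 1L
  })

  fit <- pvdm_train_cpp(indexed, counts, params$vector_size, params$window,
                        params$alpha, params$min_alpha, params$negative,
                        params$epochs, as.double(params$seed))
  colnames(fit$doc_vectors) <- ids
  colnames(fit$word_vectors) <- vocab
  structure(
    list(params = params, vocab = vocab, counts = counts,
         word_vectors = fit$word_vectors,
         output_weights = fit$output_weights,
         doc_ids = ids, doc_vectors = fit$doc_vectors),
    class = "pvdm_model"
  )
}

#' @export
print.pvdm_model <- function(x, ...) {
  cat(sprintf("<pvdm_model> %d docs, vocab %d, dim %d, epochs %d\n",
              length(x$doc_ids), length(x$vocab),
              x$params$vector_size, x$params$epochs))
  invisible(x)
}

#' Retrieve the trained vector of a corpus document
#'
#' @param model A trained [train_pvdm()] model.
#' @param doc_id Document id present in the training corpus.
#' @return Numeric vector of length `vector_size`.
#' @export
doc_vector <- function(model, doc_id) {
  stopifnot(inherits(model, "pvdm_model"))
  if (!doc_id %in% model$doc_ids) {
    abort_validation(sprintf("'%s' was not in the training corpus", doc_id))
  }
  model$doc_vectors[, doc_id]
}

#' Infer the embedding of a document under a trained model
#'
#' Gradient-descends a fresh paragraph vector against the frozen word
#' vectors and output layer. Deterministic for a fixed seed. A document
#' whose tokens are all out-of-vocabulary still yields a vector (the seeded
#' random initialization, i.e. inference from the null context) with a
#' warning.
#'
#' @param model A trained [train_pvdm()] model.
#' @param doc A tokenized document (list with `doc_id`, `tokens`).
#' @param infer_epochs Inference epochs; defaults to the training epoch
#'   count.
#' @param seed Integer seed.
#' @return Numeric vector of length `vector_size`.
#' @export
infer_vector <- function(model, doc, infer_epochs = NULL, seed = 1) {
  if (!inherits(model, "pvdm_model")) {
    abort_state("model is not a trained pvdm_model")
  }
  if (length(doc$tokens) == 0L) abort_validation("document has no tokens")
  infer_epochs <- infer_epochs %||% model$params$epochs
  idx <- match(doc$tokens, model$vocab)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) {
    warning(sprintf(
      "document '%s' has no in-vocabulary token; returning null-context vector",
      doc$doc_id %||% "?"))
  }
  p <- model$params
  pvdm_infer_cpp(as.integer(idx) - 1L, model$word_vectors,
                 model$output_weights, model$counts, p$window, p$alpha,
                 p$min_alpha, p$negative, as.integer(infer_epochs),
                 as.double(seed))
}
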