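#' Cosine similarity between two vectors
#'
#' `u . v / (||u|| ||v||)`, in `[-1, 1]`.
#'
#' @param u,v Numeric vectors of equal length, both non-zero.
#' @return A single number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort_validation("vectors differ in length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort_validation("cosine similarity undefined for a zero vector")
  }
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Score a corpus by cosine similarity to the context document
#'
#' The context pseudo-document's vector is inferred under the trained model;
#' each corpus document is scored by the cosine between its trained
#' paragraph vector and that context vector. Higher scores mean greater
#' similarity to the target (AMR) context.
#'
#' @param model A trained [train_pvdm()] model.
#' @param context The context document from [context_document()].
#' @param tokens Optional `amr_tokens` for documents not in the training
#'   corpus; their vectors are inferred instead. Default: score the training
#'   documents.
#' @param infer_epochs,seed Passed to [infer_vector()].
#' @return Data frame `doc_id, method, score` with method `"pvdm_cosine"`.
#' @export
score_corpus_pvdm <- function(model, context, tokens = NULL,
                              infer_epochs = NULL, seed = 1) {
  stopifnot(inherits(model, "pvdm_model"))
  ctx_vec <- infer_vector(model, context, infer_epochs = infer_epochs,
                          seed = seed)
  if (is.null(tokens)) {
    ids <- model$doc_ids
    vecs <- lapply(ids, function(id) model$doc_vectors[, id])
  } else {
    ids <- token_ids(tokens)
    vecs <- lapply(tokens, infer_vector, model = model,
                   infer_epochs = infer_epochs, seed = seed)
  }
  data.frame(
    doc_id = ids,
    method = "pvdm_cosine",
    score = vapply(vecs, cosine_similarity, 0.0, v = ctx_vec),
    stringsAsFactors = FALSE
  )
}

#' TF-IDF weights of lexicon terms per document
#'
#' Builds the document-by-term weight table restricted to the lexicon
#' vocabulary, columns in lexicographic term order. The variant is raw term
#' frequency times smoothed idf, `idf(t) = ln((1 + N) / (1 + df(t))) + 1`,
#' with no row normalization; tokens outside the lexicon never affect the
#' table.
#'
#' @param tokens An `amr_tokens` corpus (non-empty).
#' @param lexicon An [amr_lexicon()].
#' @return Numeric matrix, one row per document (rownames = doc ids), one
#'   column per lexicon term.
#' @export
tfidf_weights <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "amr_lexicon"))
  if (!length(lexicon)) abort_validation("lexicon is empty")
  if (!length(tokens)) abort_validation("corpus is empty")
  terms <- sort(as.character(lexicon), method = "radix")
  ids <- token_ids(tokens)
  check_doc_ids(ids)
  tf <- t(vapply(tokens, function(d) {
    tabulate(match(d$tokens, terms), nbins = length(terms))
  }, numeric(length(terms))))
  dimnames(tf) <- list(ids, terms)
  df <- colSums(tf > 0)
  idf <- log((1 + nrow(tf)) / (1 + df)) + 1
  sweep(tf, 2, idf, `*`)
}

#' Score a corpus by mean TF-IDF weight of its lexicon terms
#'
#' The bag-of-words baseline: each document's score is the arithmetic mean
#' of its TF-IDF weights over the lexicon terms it actually contains
#' (`mean_over = "present"`, the default); documents containing no lexicon
#' term score 0. `mean_over = "all"` divides by the full lexicon size
#' instead, making scores scale with lexicon size rather than content.
#'
#' @param weights Matrix from [tfidf_weights()].
#' @param mean_over Denominator convention, `"present"` or `"all"`.
#' @return Data frame `doc_id, method, score` with method
#'   `"bow_tfidf_mean"`.
#' @export
score_corpus_bow <- function(weights, mean_over = c("present", "all")) {
  mean_over <- match.arg(mean_over)
  score <- apply(weights, 1, function(w) {
    nz <- w[w > 0]
    if (!length(nz)) return(0)
    if (mean_over == "present") mean(nz) else sum(nz) / length(w)
  })
  data.frame(doc_id = rownames(weights), method = "bow_tfidf_mean",
             score = unname(score), stringsAsFactors = FALSE)
}
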