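# Builders shared across test files. Everything is generated in code; the
# only on-disk fixtures are the two recorded-style XML responses (synthetic).

# amr_tokens from a named list of token vectors.
make_tokens <- function(docs) {
  structure(
    lapply(names(docs), function(id) list(doc_id = id, tokens = docs[[id]])),
    class = "amr_tokens"
  )
}

# Small two-topic corpus for embedding property tests (cheap parameters).
small_sim <- function(seed, n = 15, len = 60) {
  generate_corpus(synthetic_spec(
    n_relevant = n, n_irrelevant = n, lexicon_size = 30,
    background_vocab_size = 200, enrichment = 0.3, background_rate = 0.05,
    doc_length_mean = len, seed = seed))
}

small_pvdm_params <- function(seed) {
  pvdm_params(vector_size = 48, epochs = 10, min_count = 2, seed = seed)
}

# Independent brute-force tf-idf oracle: explicit loops, no shared code with
# tfidf_weights().
oracle_tfidf <- function(docs, terms) {
  terms <- sort(terms)
  n <- length(docs)
  out <- matrix(0, n, length(terms), dimnames = list(names(docs), terms))
  for (j in seq_along(terms)) {
    df <- 0
    for (d in docs) if (terms[j] %in% d) df <- df + 1
    idf <- log((1 + n) / (1 + df)) + 1
    for (i in seq_len(n)) {
      out[i, j] <- sum(docs[[i]] == terms[j]) * idf
    }
  }
  out
}

# Independent recount oracle for confusion-derived metrics.
oracle_metrics <- function(pred, gold) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(gold))) {
    p <- pred$label[pred$doc_id == gold$doc_id[i]]
    g <- gold$label[i]
    if (p == 0 && g == 0) tp <- tp + 1
    if (p == 0 && g == 1) fp <- fp + 1
    if (p == 1 && g == 0) fn <- fn + 1
    if (p == 1 && g == 1) tn <- tn + 1
  }
  div <- function(a, b) if (b == 0) 0 else a / b
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  p0 <- div(tp, tp + fp); r0 <- div(tp, tp + fn)
  p1 <- div(tn, tn + fn); r1 <- div(tn, tn + fp)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision_0 = p0, recall_0 = r0, f1_0 = f1(p0, r0),
       precision_1 = p1, recall_1 = r1, f1_1 = f1(p1, r1),
       accuracy = (tp + tn) / nrow(gold))
}

fixture_path <- function(name) test_path("fixtures", name)
fixture_text <- function(name) {
  paste(readLines(fixture_path(name), warn = FALSE), collapse = "\n")
}
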