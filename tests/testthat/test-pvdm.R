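test_that("default training yields one 300-dimensional vector per document", {
  sim <- generate_corpus(synthetic_spec(n_relevant = 20, n_irrelevant = 20,
                                        doc_length_mean = 60, seed = 11))
  tok <- tokenize_corpus(sim$corpus, sim$lexicon)
  model <- train_pvdm(tok, pvdm_params(seed = 11))
  expect_identical(dim(model$doc_vectors), c(300L, 40L))
  expect_true(all(is.finite(model$doc_vectors)))
  expect_length(doc_vector(model, "SYN0001"), 300L)
})

test_that("training and inference are reproducible with a fixed seed", {
  sim <- small_sim(3)
  tok <- tokenize_corpus(sim$corpus, sim$lexicon)
  m1 <- train_pvdm(tok, small_pvdm_params(3))
  m2 <- train_pvdm(tok, small_pvdm_params(3))
  expect_identical(m1$doc_vectors, m2$doc_vectors)
  expect_identical(m1$word_vectors, m2$word_vectors)

  ctx <- context_document(sim$lexicon)
  v1 <- infer_vector(m1, ctx, seed = 9)
  v2 <- infer_vector(m1, ctx, seed = 9)
  expect_identical(v1, v2)
  expect_length(v1, 48L)
})

test_that("degenerate training inputs are rejected", {
  one <- make_tokens(list(D1 = c("a", "b", "c")))
  expect_error(train_pvdm(one, small_pvdm_params(1)),
               class = "amrtriage_validation")
  rare <- make_tokens(list(D1 = c("a", "b"), D2 = c("c", "d")))
  expect_error(train_pvdm(rare, pvdm_params(min_count = 3, seed = 1)),
               "vocabulary empty", class = "amrtriage_validation")
  expect_error(pvdm_params(dm = 0), class = "amrtriage_validation")
  expect_error(pvdm_params(min_alpha = 0.5, alpha = 0.1),
               class = "amrtriage_validation")
})

test_that("out-of-vocabulary documents still get a (flagged) vector", {
  sim <- small_sim(5)
  tok <- tokenize_corpus(sim$corpus, sim$lexicon)
  model <- train_pvdm(tok, small_pvdm_params(5))
  oov <- list(doc_id = "OOV", tokens = c("zzz", "yyy"))
  expect_warning(v <- infer_vector(model, oov, seed = 2), "no in-vocabulary")
  expect_length(v, 48L)
  expect_true(all(is.finite(v)))
  expect_error(infer_vector(list(), oov), class = "amrtriage_state")
})

test_that("trained embeddings separate the two topics and recognise their own documents", {
  # two properties on one trained model per seed: (i) a re-inferred training
  # document lands nearer its own trained vector than a random other one;
  # (ii) lexicon-rich documents score closer to the context on average
  own_hits <- 0L
  sep_wins <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    sim <- small_sim(100 + s, n = 15, len = 100)
    tok <- tokenize_corpus(sim$corpus, sim$lexicon)
    model <- train_pvdm(tok, pvdm_params(vector_size = 100, epochs = 20,
                                         min_count = 2, seed = 100 + s))
    v <- infer_vector(model, tok[[1]], seed = s)
    own <- cosine_similarity(v, doc_vector(model, tok[[1]]$doc_id))
    other_id <- model$doc_ids[[2 + (s %% 15)]]
    if (own > cosine_similarity(v, doc_vector(model, other_id))) {
      own_hits <- own_hits + 1L
    }

    sc <- score_corpus_pvdm(model, context_document(sim$lexicon), seed = s)
    expect_true(all(sc$score >= -1 & sc$score <= 1))
    cls <- sim$gold$label[match(sc$doc_id, sim$gold$doc_id)]
    if (mean(sc$score[cls == 0L]) > mean(sc$score[cls == 1L])) {
      sep_wins <- sep_wins + 1L
    }
  }
  expect_gt(own_hits, n_seeds / 2)  # majority across seeds
  # one-sided sign test at alpha = 0.05: 15+ of 20 under H0 has p < 0.021
  expect_gte(sep_wins, 15L)
})

test_that("identical copies of the context document all score the same", {
  lex <- amr_lexicon(sprintf("term%02d", 1:12))
  ctx <- context_document(lex)
  copies <- make_tokens(setNames(rep(list(ctx$tokens), 4),
                                 sprintf("C%d", 1:4)))
  model <- train_pvdm(copies, pvdm_params(vector_size = 24, epochs = 5,
                                          min_count = 2, seed = 8))
  sc <- score_corpus_pvdm(model, ctx, tokens = copies, seed = 8)
  expect_true(all(sc$score == sc$score[[1]]))
})
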