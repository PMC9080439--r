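#' Specification for a synthetic two-topic corpus
#'
#' The generator emulates a triage corpus as a unigram mixture: every token
#' of a relevant document (class 0) is drawn from the domain lexicon with
#' probability `enrichment`, otherwise from a background vocabulary;
#' irrelevant documents (class 1) use `background_rate` instead. Document
#' lengths are Poisson with mean `doc_length_mean`, truncated at 20 tokens
#' so paragraph-vector inference is never degenerate. A fifth of the lexicon
#' terms are multiword phrases, so tokenization's phrase rewriting is
#' exercised end to end.
#'
#' Defaults describe a well-separated desk-scale corpus: 50 + 50 documents,
#' a 50-term lexicon over a 500-word background vocabulary, 30% lexicon
#' tokens in relevant documents against a 5% background rate, mean length
#' 120 tokens.
#'
#' @param n_relevant,n_irrelevant Documents per class (each >= 1, total
#'   >= 4).
#' @param lexicon_size,background_vocab_size Vocabulary sizes (>= 1).
#' @param enrichment,background_rate Lexicon-draw probabilities per class,
#'   in `[0, 1]` with `enrichment > background_rate`.
#' @param doc_length_mean Mean document length in token draws.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_relevant = 50, n_irrelevant = 50,
                           lexicon_size = 50, background_vocab_size = 500,
                           enrichment = 0.3, background_rate = 0.05,
                           doc_length_mean = 120, seed = 1) {
  counts <- c(n_relevant, n_irrelevant, lexicon_size,
              background_vocab_size, doc_length_mean)
  if (!all(vapply(counts, is_count, TRUE))) {
    abort_validation("all counts must be positive integers")
  }
  if (n_relevant + n_irrelevant < 4) {
    abort_validation("need at least 4 documents in total")
  }
  if (!(enrichment >= 0 && enrichment <= 1 &&
        background_rate >= 0 && background_rate <= 1)) {
    abort_validation("rates must lie in [0, 1]")
  }
  if (enrichment <= background_rate) {
    abort_validation("enrichment must exceed background_rate")
  }
  structure(
    list(n_relevant = as.integer(n_relevant),
         n_irrelevant = as.integer(n_irrelevant),
         lexicon_size = as.integer(lexicon_size),
         background_vocab_size = as.integer(background_vocab_size),
         enrichment = enrichment, background_rate = background_rate,
         doc_length_mean = as.integer(doc_length_mean),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Surface forms: every 5th lexicon term is a two-word phrase whose
# normalized token is underscore-joined.
synthetic_lexicon_surface <- function(n) {
  ifelse(seq_len(n) %% 5L == 0L,
         sprintf("amr term %03d", seq_len(n)),
         sprintf("amrterm%03d", seq_len(n)))
}

#' Generate a labeled synthetic corpus
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `corpus` ([amr_corpus()]), `gold` (data frame
#'   `doc_id, label`), and `lexicon` ([amr_lexicon()]).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lex_surface <- synthetic_lexicon_surface(spec$lexicon_size)
  bg_vocab <- sprintf("bgword%04d", seq_len(spec$background_vocab_size))
  n_total <- spec$n_relevant + spec$n_irrelevant
  label <- rep(c(0L, 1L), c(spec$n_relevant, spec$n_irrelevant))
  rate <- ifelse(label == 0L, spec$enrichment, spec$background_rate)

  bodies <- withr::with_seed(spec$seed, {
    vapply(seq_len(n_total), function(i) {
      len <- max(20L, rpois(1, spec$doc_length_mean))
      from_lex <- runif(len) < rate[i]
      words <- character(len)
      n_lex <- sum(from_lex)
      if (n_lex) {
        words[from_lex] <- lex_surface[sample.int(spec$lexicon_size, n_lex,
                                                  replace = TRUE)]
      }
      if (len - n_lex) {
        words[!from_lex] <- bg_vocab[sample.int(spec$background_vocab_size,
                                                len - n_lex, replace = TRUE)]
      }
      paste(words, collapse = " ")
    }, "")
  })

  ids <- sprintf("SYN%04d", seq_len(n_total))
  list(
    corpus = amr_corpus(doc_id = ids, title = "", body = bodies),
    gold = data.frame(doc_id = ids, label = label, stringsAsFactors = FALSE),
    lexicon = amr_lexicon(lex_surface, source_tag = "synthetic")
  )
}

#' Draw a stratified gold test subset
#'
#' Samples `n` documents preserving the corpus class ratio (so a 15:47
#' ratio sampled at n = 62 yields 15 relevant and 47 irrelevant), emulating
#' an expert-labeled held-out test set. Reproducible from the seed.
#'
#' @param gold Data frame `doc_id, label` for the whole corpus.
#' @param n Subset size (<= corpus size).
#' @param seed Integer seed.
#' @return A stratified subset of `gold`, ordered as in `gold`.
#' @export
generate_gold_subset <- function(gold, n, seed = 1) {
  if (!is_count(n) || n > nrow(gold)) {
    abort_validation("n must be a positive count <= corpus size")
  }
  n0 <- round(n * sum(gold$label == 0L) / nrow(gold))
  n1 <- n - n0
  if (n0 > sum(gold$label == 0L) || n1 > sum(gold$label == 1L)) {
    abort_validation("requested subset exceeds a class's size")
  }
  picked <- withr::with_seed(seed, {
    c(sample(gold$doc_id[gold$label == 0L], n0),
      sample(gold$doc_id[gold$label == 1L], n1))
  })
  gold[gold$doc_id %in% picked, , drop = FALSE]
}
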