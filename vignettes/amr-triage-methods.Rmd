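---
title: "Methods: weakly supervised triage of AMR literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised triage of AMR literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Biocuration of antimicrobial-resistance (AMR) databases starts with article
selection: finding, among tens of thousands of retrieved full-text papers,
the ones actually about resistance mechanisms, genes and phenotypes.
Supervised document classification would do this well, but it needs labeled
training data that curators do not have time to produce. `amrtriage`
implements a weak-supervision alternative: label the corpus automatically by
its similarity to the AMR domain vocabulary, then train an ordinary
classifier on those automatic labels.

## The procedure

1. **Retrieval.** Articles come from PubMed Central through the E-utilities
   API (`search_pmc()`, `fetch_fulltext()`), using the MeSH expansion of
   *drug resistance, microbial* restricted to the open-access subset. Each
   JATS article is flattened to plain text as title, then abstract
   paragraphs, then body paragraphs, in document order. The flattening rule
   is this package's choice; titles and abstracts carry a large share of
   the topical signal, so they are kept.

2. **Context document.** A domain lexicon (in production, terms from CARD
   and the Gene Ontology; any one-term-per-line file works) is normalized
   and assembled into a pseudo-document (`context_document()`): each term
   once, in lexicographic order. Sorting makes the construction
   reproducible; including each term once avoids weighting the context by
   accidental duplication in the source lists. Multiword terms are rewritten
   to single underscore-joined tokens during tokenization so they survive as
   one feature.

3. **Embedding.** A PV-DM (distributed-memory paragraph vector) model is
   trained on the tokenized corpus (`train_pvdm()`): one dense vector per
   document, learned jointly with word vectors by predicting each word from
   the mean of its paragraph vector and windowed context, with negative
   sampling. Defaults: 300 dimensions, learning rate 0.025 decaying
   linearly to 0.00025, minimum word count 3, 30 epochs, `dm = 1`. Window
   half-width 5 and 5 negative samples per positive are this package's
   choices (the common PV-DM defaults); there is no frequent-word
   subsampling, which keeps single-threaded training bit-reproducible for a
   fixed seed. Training is always single-threaded (`workers = 1`):
   multi-threaded updates race and destroy reproducibility.

4. **Scoring.** The context document's vector is inferred under the trained
   model (gradient descent on a fresh paragraph vector with everything else
   frozen), and each corpus document is scored by the cosine between its
   trained vector and the context vector (`score_corpus_pvdm()`); scores
   lie in [-1, 1]. Corpus documents use their trained vectors; only the
   context (and any unseen document) is inferred. Re-inference of the whole
   corpus would be equally valid but doubles the cost for no benefit at
   this scale. Note one consequence: two byte-identical corpus documents get
   *different trained* vectors (they are independently initialized), while
   the inference path with a fixed seed maps identical token sequences to
   identical vectors.

5. **Baseline scoring.** The bag-of-words baseline (`tfidf_weights()`,
   `score_corpus_bow()`) scores a document by the arithmetic mean of its
   TF-IDF weights over lexicon terms. The TF-IDF variant is fixed and
   documented: raw term frequency times smoothed idf,
   `idf(t) = ln((1 + N)/(1 + df(t))) + 1`, no row normalization. The mean
   is taken over the lexicon terms *present* in the document
   (`mean_over = "present"`); dividing by all lexicon terms instead
   (`mean_over = "all"`) would make scores scale with lexicon size rather
   than document content. Only the score ordering matters to the
   thresholding step, so the variant choice affects robustness, not the
   method's definition.

6. **Weak labeling.** `mean_threshold_label()` labels a document relevant
   (class 0) when its score is equal to or greater than the arithmetic mean
   of all scores, irrelevant (class 1) otherwise. Ties at the mean are
   relevant; a relative epsilon of 1e-12 keeps that rule stable under
   floating-point summation noise (in doubles, `mean(c(.2, .4, .6))`
   exceeds 0.4 by 1 ulp). The mean is computed over the entire scored
   corpus, including documents later held out as the gold test set —
   hold-out applies to classifier training, not to labeling.

7. **Classification.** An RBF-kernel SVM is trained on the weak labels with
   the same TF-IDF lexicon features (`train_svm()`), after excluding the
   expert-labeled test ids. Hyperparameters are chosen by grid search —
   C in {0.1, 1, 10, 100}, gamma in {1e-3, 1e-2, 1e-1, 1, 1/n_features} —
   under stratified 5-fold cross-validated accuracy, ties broken toward
   smaller C then smaller gamma, then refit on all training rows. The grids
   are a standard log grid bracketing the RBF regimes; accuracy is the
   selection metric because it is the headline evaluation metric. Features
   are not rescaled: TF-IDF weights share a scale and many columns are
   sparse.

8. **Evaluation.** `confusion_matrix()`, `classification_metrics()` and
   `label_agreement()` compute the per-class precision/recall/F1 table,
   accuracy, and labeling-agreement percentages against expert labels, with
   class 0 (relevant) as the positive class. Metrics are reported at full
   precision alongside half-up rounding (2 decimals for metrics, nearest
   integer for percentages). A zero denominator yields 0 and a flag rather
   than NaN.

## The synthetic corpus generator

`generate_corpus()` emulates the triage setting as a unigram mixture: every
token of a relevant document is a lexicon term with probability
`enrichment` (default 0.30), otherwise a background word; irrelevant
documents use `background_rate` (default 0.05). Lengths are Poisson (mean
120) truncated at 20 tokens, so paragraph-vector inference never sees a
degenerate document. One in five lexicon terms is a two-word phrase, so the
phrase-rewriting path of the tokenizer is exercised end to end. The default
corpus is 50 relevant + 50 irrelevant documents over a 50-term lexicon and
500-word background vocabulary, and `generate_gold_subset()` draws a
stratified 30-document subset emulating the expert-labeled test set.

What the generator deliberately does not model: discourse structure, word
order semantics, topical correlation among background words, citation and
boilerplate text, and class imbalance at retrieval scale. Passing tests on
this generator therefore show that the pipeline recovers
relevance-by-lexicon-enrichment — the assumption the weak-labeling method
itself rests on — not that real PMC corpora are this easy. On the synthetic
defaults, PV-DM weak labels agree with the generating classes at 98–100%
and the bag-of-words baseline at roughly 88–94% across seeds; on real
full-text corpora both figures are substantially lower, and their *gap* is
the behavior of interest.

## Numerical choices and degenerate inputs

- PV-DM initialization is uniform in (-0.5, 0.5)/dim from a splitmix64
  generator seeded by the user; R's own RNG stream is untouched by
  training.
- The vocabulary is ordered by decreasing frequency with lexicographic
  tie-break, so vocabulary indices (and hence sampling sequences) are
  deterministic.
- Inference freezes word vectors *and* the output layer; only the new
  paragraph vector moves. A document whose tokens are all out-of-vocabulary
  yields its seeded random initialization, with a warning.
- Cosine similarity refuses zero vectors rather than returning NaN.
- Documents that tokenize to nothing are excluded from the corpus with a
  warning naming them.
- Property-style embedding tests run at a reduced scale chosen for training
  convergence (100 dimensions, 20 epochs, 30 documents of ~100 tokens);
  below that budget the embedding is undertrained and the topic-separation
  property is not yet expressed. Acceptance-level checks use the full
  default parameters.

## Known limitations

- PV-DM training is O(corpus tokens x epochs x dimension) on one thread;
  the desk-scale defaults train in seconds, a 10^5-document full-text
  corpus takes hours. The pipeline accepts that scale but the test suite
  does not attempt it.
- The mean-threshold labeler assumes the score distribution is roughly
  balanced around its mean; on corpora where relevant documents are rare,
  the mean splits poorly and a quantile threshold (not a default; see
  `mean_threshold_label()`) would be more appropriate.
- Agreement percentages are rounded half-up; reference tables produced by
  truncation can differ by one point in a per-class cell (e.g. 10/15 =
  66.7% prints as 67 here).
- The E-utilities client implements exactly the ESearch/EFetch subset the
  pipeline needs (id lists, JATS flattening); it is not a general Entrez
  client.
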