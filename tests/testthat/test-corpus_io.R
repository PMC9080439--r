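test_that("default search spec reproduces the canonical E-Search request byte for byte", {
  canonical <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi?db=pmc",
    "&term=%22drug%20resistance,%20microbial%22[MeSH%20Terms]%20OR%20",
    "(%22drug%22[All%20Fields]%20AND%20%22resistance%22[All%20Fields]%20AND",
    "%20%22microbial%22[All%20Fields])%20OR%20%22microbial%20drug%20",
    "resistance%22[All%20Fields]%20OR%20(%22drug%22[All%20Fields]%20AND%20",
    "%22resistance%22[All%20Fields]%20AND%20%22microbial%22[All%20Fields])",
    "%20OR%20%22drug%20resistance,%20microbial%22[All%20Fields])%20AND%20",
    "%22open%20access%22[filter]&retmax=10000"
  )
  expect_identical(esearch_url(search_spec()), canonical)
})

test_that("search_pmc parses IdList from a recorded response", {
  transport <- fixture_transport(fixture_text("esearch_response_synthetic.xml"))
  ids <- search_pmc(search_spec(), transport = transport)
  expect_identical(ids, c("PMC7000001", "PMC7000002", "PMC7000003"))
  expect_lte(length(ids), 10000)

  empty <- fixture_transport(
    "<eSearchResult><Count>0</Count><IdList></IdList></eSearchResult>")
  expect_identical(search_pmc(search_spec(), transport = empty), character())

  noidlist <- fixture_transport("<eSearchResult><Count>0</Count></eSearchResult>")
  expect_error(search_pmc(search_spec(), transport = noidlist),
               "IdList", class = "amrtriage_parse")
})

test_that("invalid search bounds are rejected", {
  expect_error(search_spec(retmax = 0), class = "amrtriage_validation")
  expect_error(search_spec(term = ""), class = "amrtriage_validation")
})

test_that("fetch_fulltext flattens articles and reports failures", {
  transport <- fixture_transport(
    fixture_text("efetch_two_articles_synthetic.xml"))
  corpus <- fetch_fulltext(c("PMC7000001", "PMC7000002"),
                           transport = transport)
  expect_s3_class(corpus, "amr_corpus")
  expect_identical(corpus$doc_id, c("PMC7000001", "PMC7000002"))
  expect_true(all(nzchar(trimws(corpus$body))))
  # title then abstract then body paragraphs, in document order
  expect_match(corpus$body[1],
               "^Efflux pumps in multidrug-resistant bacteria Antibiotic efflux")
  expect_match(corpus$body[1], "Overexpression confers multidrug resistance\\.$")

  # a nonexistent id is reported, not silently dropped
  expect_warning(
    partial <- fetch_fulltext(c("PMC7000001", "PMC7000002", "PMC9999999"),
                              transport = transport),
    "PMC9999999")
  expect_identical(attr(partial, "failed_ids"), "PMC9999999")
  expect_identical(nrow(partial), 2L)

  expect_error(fetch_fulltext(character()), class = "amrtriage_validation")
  expect_error(
    fetch_fulltext("PMC1", transport = fixture_transport(
      "<pmc-articleset></pmc-articleset>")),
    "empty corpus", class = "amrtriage_retrieval")
})

test_that("corpus, lexicon, scores, labels and gold round-trip through disk", {
  dir <- withr::local_tempdir()
  corpus <- amr_corpus(doc_id = c("PMC1", "PMC2", "PMC3"),
                       title = c("t1", "", "t3"),
                       body = c("efflux pumps", "beta lactamase", "plasmid"))
  p <- file.path(dir, "corpus.jsonl")
  write_corpus(corpus, p)
  expect_identical(read_corpus(p), corpus)

  lex <- amr_lexicon(c("Antibiotic Efflux", "beta-lactamase"), "CARD+GO fixture")
  pl <- file.path(dir, "lexicon.txt")
  write_lexicon(lex, pl)
  expect_identical(as.character(read_lexicon(pl)), as.character(lex))

  scores <- data.frame(doc_id = c("PMC1", "PMC2"), method = "pvdm_cosine",
                       score = c(0.25, -0.5), stringsAsFactors = FALSE)
  ps <- file.path(dir, "scores.csv")
  write_scores(scores, ps)
  expect_equal(read_scores(ps), scores)

  labels <- cbind(scores, label = c(0L, 1L))
  plb <- file.path(dir, "labels.csv")
  write_labels(labels, plb)
  expect_equal(read_labels(plb), labels)

  gold <- data.frame(doc_id = c("PMC1", "PMC2"), label = c(0L, 1L),
                     stringsAsFactors = FALSE)
  pg <- file.path(dir, "gold.csv")
  write_gold(gold, pg)
  expect_equal(read_gold(pg), gold)
})

test_that("gold files accept word labels and reject bad input", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "gold.csv")

  writeLines(c("PMC1,relevant", "PMC2,IRRELEVANT", "PMC3,0"), p)
  gold <- read_gold(p)
  expect_identical(gold$label, c(0L, 1L, 0L))

  writeLines(c("PMC1,relevant", "PMC2,maybe"), p)
  expect_error(read_gold(p), "line 2", class = "amrtriage_parse")

  writeLines(c("PMC1,0", "PMC1,1"), p)
  expect_error(read_gold(p), "duplicate", class = "amrtriage_validation")
})

test_that("corpus constructor enforces its invariants", {
  expect_error(amr_corpus(doc_id = c("A", "A"), body = c("x", "y")),
               "duplicate", class = "amrtriage_validation")
  expect_error(amr_corpus(doc_id = "A", body = "   "),
               class = "amrtriage_validation")
})
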