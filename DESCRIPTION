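Package: amrtriage
Title: Weakly Supervised Triage of Antimicrobial-Resistance Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for ranking and classifying scientific articles by their
    relevance to the antimicrobial-resistance (AMR) domain. Articles are
    retrieved from PubMed Central through the E-utilities API (or loaded from
    local JSONL corpora), scored against a domain-lexicon context document
    under two text representations (PV-DM paragraph vectors with cosine
    similarity, and TF-IDF bag-of-words mean weight), weakly labeled by
    arithmetic-mean thresholding of the scores, and used to train an
    RBF-kernel support-vector machine whose predictions are evaluated against
    an expert-labeled gold set. Includes a synthetic two-topic corpus
    generator so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stringi,
    withr,
    xml2,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
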