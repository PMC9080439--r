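#' Normalize a lexicon term or text fragment
#'
#' Unicode-normalizes (NFKC), lowercases, strips punctuation, and collapses
#' internal whitespace to a single underscore so multiword terms become one
#' token (`"Antibiotic Efflux"` -> `"antibiotic_efflux"`,
#' `"beta-lactamase"` -> `"betalactamase"`).
#'
#' @param term A non-empty string.
#' @return The normalized term.
#' @export
normalize_term <- function(term) {
  if (!is_string(term)) abort_validation("term must be a single string")
  x <- stringi::stri_trans_nfkc(term)
  x <- tolower(x)
  x <- gsub("[^[:alnum:][:space:]_]", "", x)
  x <- gsub("\\s+", "_", trimws(x))
  if (!nzchar(x)) abort_validation(sprintf("term '%s' empty after normalization", term))
  x
}

#' Construct a domain lexicon
#'
#' A lexicon is the normalized, de-duplicated term list that defines the
#' target context (for AMR: terms drawn from CARD and the Gene Ontology).
#' Original order is preserved; duplicates after normalization collapse to
#' their first occurrence.
#'
#' @param terms Character vector of terms (raw or already normalized).
#' @param source_tag Free-text provenance tag, e.g. `"CARD+GO fixture"`.
#' @return An object of class `amr_lexicon` (a character vector of
#'   normalized terms with a `source_tag` attribute).
#' @export
amr_lexicon <- function(terms, source_tag = "user") {
  if (!is.character(terms) || length(terms) == 0L) {
    abort_validation("lexicon must contain at least one term")
  }
  norm <- vapply(terms, normalize_term, "", USE.NAMES = FALSE)
  norm <- norm[!duplicated(norm)]
  structure(norm, source_tag = source_tag, class = "amr_lexicon")
}

#' @export
print.amr_lexicon <- function(x, ...) {
  cat(sprintf("<amr_lexicon> %d term(s), source: %s\n",
              length(x), attr(x, "source_tag")))
  cat("  ", paste(head(unclass(x), 6), collapse = ", "),
      if (length(x) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read and write a lexicon file (one term per line)
#'
#' @param path File path.
#' @param source_tag Provenance tag recorded on the returned lexicon.
#' @param lexicon An [amr_lexicon()].
#' @return `read_lexicon()` returns an [amr_lexicon()].
#' @export
read_lexicon <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) abort_validation(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  amr_lexicon(lines[nzchar(lines)], source_tag = source_tag)
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  writeLines(as.character(lexicon), path, useBytes = TRUE)
  invisible(path)
}

# Index multiword lexicon terms by their first word for the greedy
# left-to-right phrase matcher; longer phrases take precedence.
phrase_index <- function(lexicon) {
  words <- strsplit(as.character(lexicon), "_", fixed = TRUE)
  multi <- words[lengths(words) > 1L]
  if (!length(multi)) return(NULL)
  multi <- multi[order(-lengths(multi))]
  idx <- split(multi, vapply(multi, `[[`, "", 1L))
  idx
}

tokenize_text <- function(text, pidx) {
  x <- stringi::stri_trans_nfkc(text)
  x <- tolower(x)
  x <- gsub("[^[:alnum:][:space:]_]", "", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (is.null(pidx) || !length(toks)) return(toks)
  out <- character(length(toks))
  n_out <- 0L
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    cands <- pidx[[toks[[i]]]]
    matched <- FALSE
    if (!is.null(cands)) {
      for (phrase in cands) {  # longest first
        k <- length(phrase)
        if (i + k - 1L <= n && identical(toks[i:(i + k - 1L)], phrase)) {
          n_out <- n_out + 1L
          out[[n_out]] <- paste(phrase, collapse = "_")
          i <- i + k
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) {
      n_out <- n_out + 1L
      out[[n_out]] <- toks[[i]]
      i <- i + 1L
    }
  }
  out[seq_len(n_out)]
}

#' Tokenize documents against a lexicon
#'
#' Text is NFKC-normalized, lowercased, punctuation-stripped and
#' whitespace-split; maximal left-to-right phrase matching first rewrites
#' in-text occurrences of multiword lexicon terms into their underscore
#' token, so every lexicon term survives as a single feature. No stemming
#' and no stop-word removal are applied.
#'
#' @param corpus An [amr_corpus()] (or a one-row slice).
#' @param lexicon An [amr_lexicon()].
#' @return A list of class `amr_tokens`: per document, a list with `doc_id`
#'   and `tokens`. Documents whose token stream is empty are excluded with a
#'   warning.
#' @export
tokenize_corpus <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "amr_corpus"), inherits(lexicon, "amr_lexicon"))
  pidx <- phrase_index(lexicon)
  docs <- lapply(seq_len(nrow(corpus)), function(i) {
    list(doc_id = corpus$doc_id[i],
         tokens = tokenize_text(paste(corpus$title[i], corpus$body[i]), pidx))
  })
  empty <- vapply(docs, function(d) length(d$tokens) == 0L, TRUE)
  if (any(empty)) {
    warning(sprintf("excluding %d document(s) with empty token stream: %s",
                    sum(empty),
                    paste(corpus$doc_id[empty], collapse = ", ")))
    docs <- docs[!empty]
  }
  structure(docs, class = "amr_tokens")
}

#' @export
print.amr_tokens <- function(x, ...) {
  lens <- vapply(x, function(d) length(d$tokens), 0L)
  cat(sprintf("<amr_tokens> %d document(s), median length %d tokens\n",
              length(x), if (length(lens)) as.integer(stats::median(lens)) else 0L))
  invisible(x)
}

token_ids <- function(tokens) vapply(tokens, `[[`, "", "doc_id")

#' Build the context pseudo-document from a lexicon
#'
#' The context document carries the lexicon's normalized terms, each once,
#' in lexicographic order (deterministic), under the reserved id
#' `"__context__"`. Its inferred embedding represents the target topic that
#' corpus documents are scored against.
#'
#' @param lexicon An [amr_lexicon()].
#' @return A single tokenized document (list with `doc_id`, `tokens`).
#' @export
context_document <- function(lexicon) {
  stopifnot(inherits(lexicon, "amr_lexicon"))
  if (!length(lexicon)) abort_validation("lexicon is empty")
  list(doc_id = "__context__",
       tokens = sort(as.character(lexicon), method = "radix"))
}
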