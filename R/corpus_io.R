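#' Default PubMed Central query for the antimicrobial-resistance domain
#'
#' The MeSH expansion of "drug resistance, microbial" combined with keyword
#' fallbacks, exactly as the canonical recorded E-Search request encodes it.
#' The trailing unmatched parenthesis is intentional: it reproduces the
#' recorded request byte-for-byte.
#'
#' @return A single query string suitable for [search_spec()].
#' @export
amr_default_query <- function() {
  paste0(
    '"drug resistance, microbial"[MeSH Terms]',
    ' OR ("drug"[All Fields] AND "resistance"[All Fields] AND "microbial"[All Fields])',
    ' OR "microbial drug resistance"[All Fields]',
    ' OR ("drug"[All Fields] AND "resistance"[All Fields] AND "microbial"[All Fields])',
    ' OR "drug resistance, microbial"[All Fields])'
  )
}

#' Specify an E-Search request
#'
#' @param db Entrez database, default `"pmc"` (full-text articles).
#' @param term Query expression; defaults to [amr_default_query()].
#' @param retmax Maximum number of ids to retrieve (>= 1).
#' @param open_access_only Restrict to the open-access subset by appending
#'   `AND "open access"[filter]` to the term.
#' @return An object of class `search_spec`.
#' @export
search_spec <- function(db = "pmc", term = amr_default_query(),
                        retmax = 10000, open_access_only = TRUE) {
  if (!is_string(term) || !nzchar(term)) abort_validation("term must be non-empty")
  if (!is_count(retmax)) abort_validation("retmax must be a positive integer")
  structure(
    list(db = db, term = term, retmax = as.integer(retmax),
         open_access_only = isTRUE(open_access_only)),
    class = "search_spec"
  )
}

eutils_base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"

# Minimal percent-encoding matching how the canonical request encodes a
# query term: spaces and double quotes only; brackets, parentheses and
# commas are sent literally.
encode_term <- function(x) {
  x <- gsub('"', "%22", x, fixed = TRUE)
  gsub(" ", "%20", x, fixed = TRUE)
}

#' Build the E-Search request URL for a spec
#'
#' @param spec A [search_spec()].
#' @return The request URL as a string.
#' @export
esearch_url <- function(spec) {
  stopifnot(inherits(spec, "search_spec"))
  term <- spec$term
  if (spec$open_access_only) term <- paste0(term, ' AND "open access"[filter]')
  sprintf("%s/esearch.fcgi?db=%s&term=%s&retmax=%d",
          eutils_base, spec$db, encode_term(term), spec$retmax)
}

#' HTTP transport reading a URL with base connections
#'
#' Transports are plain functions `url -> response text`, so tests can inject
#' recorded fixtures ([fixture_transport()]) and live retrieval stays a thin
#' replaceable layer.
#'
#' @param delay Politeness delay in seconds before each request (NCBI asks
#'   for at most 3 requests/second without an API key).
#' @return A transport function.
#' @export
pmc_transport <- function(delay = 0.34) {
  force(delay)
  function(url) {
    if (delay > 0) Sys.sleep(delay)
    con <- url(url, open = "rb")
    on.exit(close(con))
    txt <- tryCatch(
      readLines(con, warn = FALSE, encoding = "UTF-8"),
      error = function(e) abort_retrieval(
        sprintf("transport failure for %s: %s", url, conditionMessage(e))
      )
    )
    paste(txt, collapse = "\n")
  }
}

#' Transport serving recorded responses
#'
#' @param responses Either a single string (served for every request) or a
#'   named list/character vector mapping exact request URLs to response text.
#' @return A transport function.
#' @export
fixture_transport <- function(responses) {
  force(responses)
  function(url) {
    if (is.character(responses) && is.null(names(responses)) &&
        length(responses) == 1L) {
      return(responses)
    }
    if (!url %in% names(responses)) {
      abort_retrieval(sprintf("no recorded response for %s", url),
                      retryable = FALSE)
    }
    responses[[url]]
  }
}

parse_xml_response <- function(txt, what) {
  tryCatch(
    xml2::read_xml(txt),
    error = function(e) abort_parse(
      sprintf("malformed %s response: %s", what, conditionMessage(e))
    )
  )
}

#' Search PubMed Central for article ids
#'
#' Issues an E-Search request and parses the returned `<IdList>`. Ids are
#' returned in service order, prefixed "PMC" when the database is pmc.
#'
#' @param spec A [search_spec()].
#' @param transport A transport function; defaults to live HTTP.
#' @return Character vector of article ids (possibly empty).
#' @export
search_pmc <- function(spec, transport = pmc_transport()) {
  stopifnot(inherits(spec, "search_spec"))
  doc <- parse_xml_response(transport(esearch_url(spec)), "E-Search")
  if (!length(xml2::xml_find_all(doc, "//IdList"))) {
    abort_parse("malformed E-Search response: missing IdList element")
  }
  ids <- xml2::xml_text(xml2::xml_find_all(doc, "//IdList/Id"))
  if (identical(spec$db, "pmc") && length(ids)) {
    ids <- ifelse(grepl("^PMC", ids), ids, paste0("PMC", ids))
  }
  ids
}

efetch_url <- function(ids, db = "pmc") {
  sprintf("%s/efetch.fcgi?db=%s&id=%s",
          eutils_base, db, paste(sub("^PMC", "", ids), collapse = ","))
}

# Flatten one JATS <article>: title, abstract paragraphs, body paragraphs,
# in document order, whitespace-normalized and space-joined.
flatten_article <- function(article) {
  title <- xml2::xml_text(
    xml2::xml_find_first(article, ".//front//article-title")
  )
  if (is.na(title)) title <- ""
  parts <- xml2::xml_text(xml2::xml_find_all(
    article, ".//front//abstract//p | .//body//p"
  ))
  body <- trimws(gsub("\\s+", " ", paste(c(title, parts), collapse = " ")))
  pmcid <- xml2::xml_text(xml2::xml_find_first(
    article,
    ".//article-meta/article-id[@pub-id-type='pmc' or @pub-id-type='pmcid']"
  ))
  if (is.na(pmcid)) return(NULL)
  if (!grepl("^PMC", pmcid)) pmcid <- paste0("PMC", pmcid)
  list(doc_id = pmcid, title = trimws(title), body = body)
}

#' Fetch full-text articles from PubMed Central
#'
#' Retrieves the listed ids in batches through E-Fetch and flattens each
#' JATS article to plain text (title, then abstract paragraphs, then body
#' paragraphs, in document order). Ids that do not resolve to retrievable
#' full text are reported in the `failed_ids` attribute and a warning, never
#' silently dropped.
#'
#' @param ids Character vector of PMCIDs (non-empty).
#' @param batch_size Ids per E-Fetch request (default 200, per NCBI usage
#'   guidance).
#' @param transport A transport function; defaults to live HTTP.
#' @return An [amr_corpus()] with attribute `failed_ids`.
#' @export
fetch_fulltext <- function(ids, batch_size = 200, transport = pmc_transport()) {
  if (!is.character(ids) || length(ids) == 0L) {
    abort_validation("ids must be a non-empty character vector")
  }
  if (!is_count(batch_size)) abort_validation("batch_size must be >= 1")
  docs <- list()
  for (start in seq(1L, length(ids), by = batch_size)) {
    batch <- ids[start:min(start + batch_size - 1L, length(ids))]
    doc <- parse_xml_response(transport(efetch_url(batch)), "E-Fetch")
    for (article in xml2::xml_find_all(doc, "//article")) {
      flat <- flatten_article(article)
      if (!is.null(flat) && nzchar(flat$body)) docs[[flat$doc_id]] <- flat
    }
  }
  failed <- setdiff(ids, names(docs))
  if (length(docs) == 0L) {
    abort_retrieval("no id resolved to retrievable full text (empty corpus)",
                    retryable = FALSE)
  }
  if (length(failed)) {
    warning(sprintf("failed to retrieve %d id(s): %s",
                    length(failed), paste(failed, collapse = ", ")))
  }
  corpus <- amr_corpus(
    doc_id = vapply(docs, `[[`, "", "doc_id"),
    title  = vapply(docs, `[[`, "", "title"),
    body   = vapply(docs, `[[`, "", "body")
  )
  attr(corpus, "failed_ids") <- failed
  corpus
}

#' Construct a document corpus
#'
#' A corpus is a data frame with columns `doc_id`, `title`, `body`; ids are
#' unique and every body is non-empty after whitespace stripping.
#'
#' @param doc_id,title,body Character vectors of equal length.
#' @return A data frame of class `amr_corpus`.
#' @export
amr_corpus <- function(doc_id = character(), title = "", body = character()) {
  out <- data.frame(doc_id = as.character(doc_id),
                    title = as.character(title),
                    body = as.character(body),
                    stringsAsFactors = FALSE, row.names = NULL)
  check_doc_ids(out$doc_id)
  if (any(!nzchar(trimws(out$body)))) {
    abort_validation("document body empty after whitespace stripping")
  }
  class(out) <- c("amr_corpus", "data.frame")
  out
}

#' @export
print.amr_corpus <- function(x, ...) {
  cat(sprintf("<amr_corpus> %d document(s)\n", nrow(x)))
  if (nrow(x)) {
    preview <- substr(x$body[seq_len(min(3L, nrow(x)))], 1, 50)
    cat(sprintf("  %s: %s...\n", x$doc_id[seq_along(preview)], preview), sep = "")
  }
  invisible(x)
}

#' Read and write corpora as JSON lines
#'
#' One document per line with fields `doc_id`, `title`, `body`; streamable
#' at 10^5-document scale.
#'
#' @param path File path.
#' @param corpus An [amr_corpus()].
#' @return `read_corpus()` returns an [amr_corpus()]; `write_corpus()`
#'   returns `path` invisibly.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[[i]]),
             error = function(e) abort_parse(
               sprintf("corpus line %d is not valid JSON: %s",
                       i, conditionMessage(e))))
  })
  amr_corpus(
    doc_id = vapply(recs, function(r) r$doc_id %||% "", ""),
    title  = vapply(recs, function(r) r$title %||% "", ""),
    body   = vapply(recs, function(r) r$body %||% "", "")
  )
}

#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "amr_corpus"))
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(doc_id = corpus$doc_id[i], title = corpus$title[i],
                          body = corpus$body[i]), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

normalize_label_token <- function(tok, where) {
  tok <- tolower(trimws(tok))
  if (tok %in% c("0", "relevant")) return(0L)
  if (tok %in% c("1", "irrelevant")) return(1L)
  abort_parse(sprintf("unknown label token '%s' at %s", tok, where))
}

#' Read an expert-labeled gold file
#'
#' Delimited `doc_id,label` (header optional) with labels in `{0, 1}` or
#' `{relevant, irrelevant}`; the canonical encoding is numeric with
#' 0 = relevant.
#'
#' @param path File path.
#' @return Data frame with columns `doc_id`, `label`.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^doc_id\\s*,", lines[[1]])) lines <- lines[-1]
  if (!length(lines)) abort_parse("gold file contains no records")
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    abort_parse(sprintf("gold line %d is not 'doc_id,label'", bad[[1]]))
  }
  out <- data.frame(
    doc_id = trimws(vapply(parts, `[[`, "", 1L)),
    label = vapply(seq_along(parts), function(i) {
      normalize_label_token(parts[[i]][[2]], sprintf("line %d", i))
    }, 0L),
    stringsAsFactors = FALSE
  )
  check_doc_ids(out$doc_id)
  out
}

#' @rdname read_gold
#' @param gold Data frame with columns `doc_id`, `label`.
#' @export
write_gold <- function(gold, path) {
  write.csv(gold[, c("doc_id", "label")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write score and label tables
#'
#' Scores are CSV `doc_id,method,score`; labels add a `label` column.
#'
#' @param path File path.
#' @param scores,labels Data frames as produced by the scoring and labeling
#'   steps.
#' @return The read functions return data frames; writers return `path`
#'   invisibly.
#' @export
read_scores <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("doc_id", "method", "score") %in% names(out))) {
    abort_parse("score file must have columns doc_id, method, score")
  }
  check_doc_ids(out$doc_id)
  out[, c("doc_id", "method", "score")]
}

#' @rdname read_scores
#' @export
write_scores <- function(scores, path) {
  write.csv(scores[, c("doc_id", "method", "score")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_scores
#' @export
read_labels <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("doc_id", "method", "score", "label")
  if (!all(need %in% names(out))) {
    abort_parse("label file must have columns doc_id, method, score, label")
  }
  out$label <- vapply(seq_len(nrow(out)), function(i) {
    normalize_label_token(as.character(out$label[i]), sprintf("row %d", i))
  }, 0L)
  check_doc_ids(out$doc_id)
  out[, need]
}

#' @rdname read_scores
#' @export
write_labels <- function(labels, path) {
  write.csv(labels[, c("doc_id", "method", "score", "label")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
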