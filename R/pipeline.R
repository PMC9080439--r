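#' Pipeline configuration
#'
#' One declarative configuration drives every stage; defaults reproduce the
#' standard protocol (PMC open-access AMR query, retmax 10000, the PV-DM
#' parameters of [pvdm_params()], 5-fold SVM grid search). The global seed
#' is propagated to the synthetic generator, embedding, gold-subset draw and
#' fold construction.
#'
#' @param output_dir Directory for stage artifacts (created if needed).
#' @param method Labeling representation driving score/label/train:
#'   `"pvdm"` or `"bow"`.
#' @param corpus,lexicon,gold Optional paths to existing inputs; when
#'   absent, `simulate` (or `fetch`) must produce them.
#' @param search A [search_spec()] for the fetch stage.
#' @param embedding A [pvdm_params()].
#' @param svm An [svm_config()].
#' @param bow List of bag-of-words options (`mean_over`).
#' @param synthetic A [synthetic_spec()] for the simulate stage.
#' @param gold_subset_n Size of the stratified expert-emulating test subset
#'   drawn by simulate (default 30).
#' @param seed Global integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, method = c("pvdm", "bow"),
                            corpus = NULL, lexicon = NULL, gold = NULL,
                            search = search_spec(),
                            embedding = pvdm_params(),
                            svm = svm_config(),
                            bow = list(mean_over = "present"),
                            synthetic = synthetic_spec(),
                            gold_subset_n = 30, seed = 1) {
  method <- match.arg(method)
  seed <- as.integer(seed)
  synthetic$seed <- seed
  embedding$seed <- seed
  svm$seed <- seed
  structure(
    list(output_dir = output_dir, method = method, corpus = corpus,
         lexicon = lexicon, gold = gold, search = search,
         embedding = embedding, svm = svm, bow = bow,
         synthetic = synthetic, gold_subset_n = as.integer(gold_subset_n),
         seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' nested `embedding`, `svm`, `search` and `synthetic` blocks override the
#' corresponding defaults field by field.
#'
#' @param path YAML file path.
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("no such config: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$output_dir)) abort_validation("config must set output_dir")
  merge_into <- function(ctor, overrides) {
    do.call(ctor, overrides %||% list())
  }
  pipeline_config(
    output_dir = y$output_dir,
    method = y$method %||% "pvdm",
    corpus = y$corpus, lexicon = y$lexicon, gold = y$gold,
    search = merge_into(search_spec, y$search),
    embedding = merge_into(pvdm_params, y$embedding),
    svm = merge_into(svm_config, y$svm),
    bow = y$bow %||% list(mean_over = "present"),
    synthetic = merge_into(synthetic_spec, y$synthetic),
    gold_subset_n = y$gold_subset_n %||% 30,
    seed = y$seed %||% 1
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_recursive(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  if (is.function(x)) return(NULL)
  x
}

artifact_paths <- function(config) {
  d <- config$output_dir
  m <- config$method
  list(
    corpus = config$corpus %||% file.path(d, "corpus.jsonl"),
    lexicon = config$lexicon %||% file.path(d, "lexicon.txt"),
    gold = config$gold %||% file.path(d, "gold.csv"),
    gold_subset = file.path(d, "gold_subset.csv"),
    scores = file.path(d, sprintf("scores_%s.csv", m)),
    labels = file.path(d, sprintf("labels_%s.csv", m)),
    threshold = file.path(d, sprintf("threshold_%s.json", m)),
    model = file.path(d, sprintf("model_%s.rds", m)),
    predictions = file.path(d, sprintf("predictions_%s.csv", m)),
    evaluation = file.path(d, sprintf("evaluation_%s.json", m)),
    manifest = file.path(d, "manifest.json")
  )
}

# Write through a temp file in the same directory, then rename: a stage
# artifact is either absent or complete, never half-written.
atomic_write <- function(writer, path) {
  tmp <- file.path(dirname(path), paste0(".tmp_", basename(path)))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    abort_state(sprintf(
      "missing input '%s'; run stage '%s' first", basename(path), producer))
  }
  path
}

pipeline_stages <- c("fetch", "simulate", "score", "label", "train", "evaluate")

#' Run the triage pipeline
#'
#' Executes the requested stages in canonical order (`fetch`/`simulate` ->
#' `score` -> `label` -> `train` -> `evaluate`). Each stage writes its
#' artifact atomically under `output_dir`; a manifest records the
#' configuration hash, the seed, and per-stage outcomes. A stage whose
#' artifact already exists under an unchanged configuration is skipped
#' unless `force = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of `fetch`, `simulate`, `score`, `label`, `train`,
#'   `evaluate`.
#' @param force Re-run stages whose artifacts are already current.
#' @param transport Transport for the fetch stage (injectable for tests).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, stages = c("simulate", "score", "label",
                                            "train", "evaluate"),
                         force = FALSE, transport = pmc_transport()) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) {
    abort_validation(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- artifact_paths(config)
  hash <- config_hash(config)

  manifest <- if (file.exists(paths$manifest)) {
    jsonlite::read_json(paths$manifest)
  } else {
    list(config_hash = hash, seed = config$seed, stages = list())
  }
  if (!identical(manifest$config_hash, hash)) {
    manifest <- list(config_hash = hash, seed = config$seed, stages = list())
  }

  current <- function(stage, outputs) {
    !force && all(file.exists(unlist(outputs))) &&
      identical(manifest$stages[[stage]]$status %||% "", "done")
  }
  record <- function(stage, status, outputs) {
    manifest$stages[[stage]] <<- list(
      status = status, outputs = basename(unlist(outputs)),
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    atomic_write(function(p) jsonlite::write_json(
      manifest, p, auto_unbox = TRUE, digits = NA), paths$manifest)
  }

  runners <- list(
    fetch = function() {
      ids <- search_pmc(config$search, transport = transport)
      corpus <- fetch_fulltext(ids, transport = transport)
      atomic_write(function(p) write_corpus(corpus, p), paths$corpus)
      list(paths$corpus)
    },
    simulate = function() {
      sim <- generate_corpus(config$synthetic)
      gold_sub <- generate_gold_subset(sim$gold, config$gold_subset_n,
                                       seed = config$seed)
      atomic_write(function(p) write_corpus(sim$corpus, p), paths$corpus)
      atomic_write(function(p) write_lexicon(sim$lexicon, p), paths$lexicon)
      atomic_write(function(p) write_gold(sim$gold, p), paths$gold)
      atomic_write(function(p) write_gold(gold_sub, p), paths$gold_subset)
      list(paths$corpus, paths$lexicon, paths$gold, paths$gold_subset)
    },
    score = function() {
      corpus <- read_corpus(require_artifact(paths$corpus, "simulate (or fetch)"))
      lexicon <- read_lexicon(require_artifact(paths$lexicon, "simulate"))
      tokens <- tokenize_corpus(corpus, lexicon)
      scores <- if (config$method == "pvdm") {
        model <- train_pvdm(tokens, config$embedding)
        score_corpus_pvdm(model, context_document(lexicon),
                          seed = config$seed)
      } else {
        score_corpus_bow(tfidf_weights(tokens, lexicon),
                         mean_over = config$bow$mean_over %||% "present")
      }
      atomic_write(function(p) write_scores(scores, p), paths$scores)
      list(paths$scores)
    },
    label = function() {
      scores <- read_scores(require_artifact(paths$scores, "score"))
      res <- mean_threshold_label(scores)
      atomic_write(function(p) write_labels(res$labels, p), paths$labels)
      atomic_write(function(p) jsonlite::write_json(
        res$summary, p, auto_unbox = TRUE, digits = NA), paths$threshold)
      list(paths$labels, paths$threshold)
    },
    train = function() {
      corpus <- read_corpus(require_artifact(paths$corpus, "simulate (or fetch)"))
      lexicon <- read_lexicon(require_artifact(paths$lexicon, "simulate"))
      labels <- read_labels(require_artifact(paths$labels, "label"))
      gold_sub <- read_gold(require_artifact(paths$gold_subset, "simulate"))
      tokens <- tokenize_corpus(corpus, lexicon)
      features <- featurize(tokens, lexicon)
      model <- train_svm(features, labels, config$svm,
                         exclude_ids = gold_sub$doc_id)
      held_out <- features[rownames(features) %in% gold_sub$doc_id, ,
                           drop = FALSE]
      preds <- predict(model, held_out)
      atomic_write(function(p) save_classifier(model, p), paths$model)
      atomic_write(function(p) write_labels(preds, p), paths$predictions)
      list(paths$model, paths$predictions)
    },
    evaluate = function() {
      preds <- read_labels(require_artifact(paths$predictions, "train"))
      labels <- read_labels(require_artifact(paths$labels, "label"))
      gold_sub <- read_gold(require_artifact(paths$gold_subset, "simulate"))
      m <- classification_metrics(confusion_matrix(preds, gold_sub))
      weak <- labels[labels$doc_id %in% gold_sub$doc_id, , drop = FALSE]
      agr <- list(weak_labels = label_agreement(weak, gold_sub),
                  svm = label_agreement(preds, gold_sub))
      atomic_write(function(p) write_evaluation(m, p, agreement = agr),
                   paths$evaluation)
      list(paths$evaluation)
    }
  )

  for (stage in stages) {
    outputs <- switch(stage,
      fetch = list(paths$corpus),
      simulate = list(paths$corpus, paths$lexicon, paths$gold,
                      paths$gold_subset),
      score = list(paths$scores),
      label = list(paths$labels, paths$threshold),
      train = list(paths$model, paths$predictions),
      evaluate = list(paths$evaluation))
    if (current(stage, outputs)) {
      message(sprintf("[%s] up to date, skipping", stage))
      next
    }
    t0 <- Sys.time()
    outs <- tryCatch(runners[[stage]](), error = function(e) {
      record(stage, "failed", outputs)
      abort_state(sprintf("stage '%s' failed: %s", stage,
                          conditionMessage(e)))
    })
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    record(stage, "done", outs)
  }
  invisible(manifest)
}
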