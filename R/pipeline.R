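# End-to-end cascade: NER -> NER repair rules -> relation extraction ->
# relation recovery rules -> scoring. Entities are predicted first and
# relations classified over the predicted entities, so entity errors
# propagate (the cascade property: end-to-end relation F1 never beats
# relation F1 over gold entities).

#' Pipeline configuration
#'
#' @param corpusDir directory with `train/`, `dev/`, `test/` standoff
#'   subdirectories.
#' @param modelDir directory receiving (or holding) the serialized
#'   artifacts: `tagger.rds`, `relclf.rds`, `vocab.txt`, `manifest.json`.
#' @param taggerSeed,taggerEpochs tagger training controls.
#' @param classifierSeed,threshold relation classifier controls.
#' @param nerRules,relationRules rule-set switches.
#' @param satAqStrategy trigger-choice strategy for [mergeSatAqAndLink()].
#' @param vocabSize subword vocabulary budget.
#' @return a named list.
#' @export
pipelineConfig <- function(corpusDir = "corpus", modelDir = "models",
                           taggerSeed = 42L, taggerEpochs = 5L,
                           classifierSeed = 42L, threshold = 0.5,
                           nerRules = TRUE, relationRules = TRUE,
                           satAqStrategy = "nearest", vocabSize = 2000L) {
  list(corpusDir = corpusDir, modelDir = modelDir,
       taggerSeed = as.integer(taggerSeed),
       taggerEpochs = as.integer(taggerEpochs),
       classifierSeed = as.integer(classifierSeed), threshold = threshold,
       nerRules = isTRUE(nerRules), relationRules = isTRUE(relationRules),
       satAqStrategy = satAqStrategy, vocabSize = as.integer(vocabSize))
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [pipelineConfig()]
#' defaults.
#'
#' @param path YAML file.
#' @return a configuration list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, raw)
}

#' Train all pipeline artifacts
#'
#' Reads the training corpus, tokenizes it, builds the subword vocabulary,
#' trains the sequence tagger and the relation classifier, and serializes
#' all three with a manifest recording the configuration, seeds and corpus
#' statistics.
#'
#' @param config see [pipelineConfig()].
#' @param trainDocs optional list of documents (overrides
#'   `config$corpusDir/train`).
#' @return invisible list with `tagger`, `classifier`, `vocab`, `manifest`.
#' @export
runTrain <- function(config, trainDocs = NULL) {
  if (is.null(trainDocs)) {
    dir <- file.path(config$corpusDir, "train")
    if (!dir.exists(dir)) stop("training corpus directory not found: ", dir)
    trainDocs <- readCorpus(dir)
  }
  if (!length(trainDocs)) stop("training corpus is empty")
  trainDocs <- lapply(trainDocs, function(d)
    if (nrow(tokens(d))) d else tokenizeDocument(d))
  vocab <- buildVocabulary(trainDocs, maxSize = config$vocabSize)
  tagger <- trainTagger(trainDocs, taggerConfig(seed = config$taggerSeed,
                                                epochs = config$taggerEpochs))
  classifier <- trainRelationClassifier(
    trainDocs, relationConfig(seed = config$classifierSeed,
                              threshold = config$threshold))
  dir.create(config$modelDir, recursive = TRUE, showWarnings = FALSE)
  saveTagger(tagger, file.path(config$modelDir, "tagger.rds"))
  saveRelationClassifier(classifier, file.path(config$modelDir, "relclf.rds"))
  writeVocabulary(vocab, file.path(config$modelDir, "vocab.txt"))
  stats <- corpusStats(trainDocs)
  manifest <- list(config = config,
                   seeds = list(tagger = config$taggerSeed,
                                classifier = config$classifierSeed),
                   corpus = list(documents = stats$documents,
                                 sentences = stats$sentences,
                                 tokens = stats$tokens),
                   artifacts = c("tagger.rds", "relclf.rds", "vocab.txt"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(config$modelDir, "manifest.json"))
  invisible(list(tagger = tagger, classifier = classifier, vocab = vocab,
                 manifest = manifest))
}

loadArtifacts <- function(config) {
  paths <- file.path(config$modelDir, c("tagger.rds", "relclf.rds"))
  if (!all(file.exists(paths)))
    stop("missing model artifacts under ", config$modelDir,
         "; run runTrain() first")
  list(tagger = loadTagger(paths[[1L]]),
       classifier = loadRelationClassifier(paths[[2L]]))
}

#' Run the prediction cascade over documents
#'
#' NER, then the NER repair rules, then within-sentence relation
#' classification, then the cross-sentence relation recovery rules.
#'
#' @param config see [pipelineConfig()].
#' @param docs list of documents (annotations, if any, are ignored); or
#'   `NULL` to read `inputDir`.
#' @param inputDir standoff directory to read when `docs` is `NULL`.
#' @param outputDir optional directory receiving predicted standoff pairs.
#' @param artifacts optional preloaded artifact list (from [runTrain()]).
#' @return list of annotated documents.
#' @export
runPredict <- function(config, docs = NULL, inputDir = NULL, outputDir = NULL,
                       artifacts = NULL) {
  if (is.null(docs)) {
    if (is.null(inputDir)) stop("either docs or inputDir must be given")
    docs <- readCorpus(inputDir)
  }
  if (!length(docs)) return(list())
  if (is.null(artifacts)) artifacts <- loadArtifacts(config)
  docs <- lapply(docs, function(d)
    if (nrow(tokens(d))) d else tokenizeDocument(d))
  out <- predictCorpus(artifacts$tagger, docs)
  out <- lapply(out, function(d) {
    if (config$nerRules) d <- applyNerRules(d)
    rel <- predictRelations(artifacts$classifier, d)
    d@relations <- rel
    validObject(d)
    if (config$relationRules)
      d <- applyRelationRules(d, satAqStrategy = config$satAqStrategy)
    d
  })
  if (!is.null(outputDir)) writeCorpus(out, outputDir)
  out
}

#' Score predictions in all modes
#'
#' Produces NER and relation reports in both exact and relaxed matching.
#' When the predicted documents come from [runPredict()] the relation
#' reports are end-to-end scores (relations over predicted entities).
#'
#' @param goldDocs,predDocs aligned document lists.
#' @param task relation-task name used in the relation reports
#'   (`"end_to_end"` for pipeline output, `"relation"` for classification
#'   over gold entities).
#' @param outDir optional directory receiving one JSON report per
#'   task/mode.
#' @return named list of [EvalReport-class] (`ner_exact`, `ner_relaxed`,
#'   `<task>_exact`, `<task>_relaxed`).
#' @export
runEvaluate <- function(goldDocs, predDocs, task = "end_to_end",
                        outDir = NULL) {
  reports <- list(
    ner_exact = score(goldDocs, predDocs, "ner", "exact"),
    ner_relaxed = score(goldDocs, predDocs, "ner", "relaxed"))
  reports[[paste0(task, "_exact")]] <-
    score(goldDocs, predDocs, task, "exact")
  reports[[paste0(task, "_relaxed")]] <-
    score(goldDocs, predDocs, task, "relaxed")
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reports))
      reportJSON(reports[[nm]], file.path(outDir, paste0(nm, ".json")))
  }
  reports
}

#' Train, predict and evaluate in one call
#'
#' @param config see [pipelineConfig()].
#' @param split which gold split to predict and score.
#' @return list with `artifacts`, `predictions`, `reports`.
#' @export
runAll <- function(config, split = "test") {
  artifacts <- runTrain(config)
  goldDir <- file.path(config$corpusDir, split)
  gold <- readCorpus(goldDir)
  pred <- runPredict(config, docs = gold, artifacts = artifacts)
  reports <- runEvaluate(lapply(gold, tokenizeDocument), pred,
                         task = "end_to_end")
  list(artifacts = artifacts, predictions = pred, reports = reports)
}
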