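# Trigger-argument relation extraction. Candidate pairs are formed within
# sentences (every event trigger x every semantic role), each candidate is
# represented by the sentence with all entity mentions replaced by their
# semantic types (entity-type masking), and a binary classifier accepts or
# rejects the pair. The ARG1/ARGM label is then assigned deterministically
# from the argument's role.

#' Generate within-sentence trigger x role candidate pairs
#'
#' For each sentence, the Cartesian product of its trigger mentions and its
#' semantic-role mentions. `EXAMPLE_LABEL` mentions are excluded: the example
#' heading identifier is never a relation argument in the scheme.
#' Cross-sentence pairs are never generated; those are recovered only by the
#' postprocessing rules.
#'
#' @param doc a tokenized [Document-class] with entities.
#' @return data.frame with columns `sentence`, `trigger`, `argument`
#'   (entity ids).
#' @export
generateCandidates <- function(doc) {
  ent <- entities(doc)
  sen <- sentences(doc)
  out <- list()
  if (nrow(ent) && nrow(sen)) {
    # sentence index of each entity: the span containing its start
    si <- vapply(ent$start, function(s)
      which(sen$start <= s & s < sen$end)[1L], integer(1L))
    for (s in sort(unique(si[!is.na(si)]))) {
      here <- ent[which(si == s), , drop = FALSE]
      trig <- here$id[isTrigger(here$label)]
      role <- here$id[!isTrigger(here$label) & here$label != "EXAMPLE_LABEL"]
      if (length(trig) && length(role))
        out[[length(out) + 1L]] <- expand.grid(sentence = s, trigger = trig,
                                               argument = role,
                                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sentence = integer(), trigger = character(),
                      argument = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Entity-type masking of a candidate pair's sentence
#'
#' Returns the sentence token sequence with every entity mention's token run
#' collapsed to a single token equal to its label name (all mentions are
#' masked, not only the focus pair), plus the masked-sequence positions of
#' the focus trigger and argument.
#'
#' @param doc a tokenized [Document-class].
#' @param pair one-row data.frame from [generateCandidates()] (or a list with
#'   `sentence`, `trigger`, `argument`).
#' @return list with `tokens` (character), `triggerPos`, `argumentPos`.
#' @export
maskPair <- function(doc, pair) {
  ent <- entities(doc)
  if (!all(c(pair$trigger, pair$argument) %in% ent$id))
    stop("candidate pair does not belong to this document")
  toks <- tokens(doc)
  sel <- which(toks$sentence == pair$sentence)
  if (!length(sel)) stop("candidate pair names a sentence with no tokens")
  st <- toks$start[sel]; en <- toks$end[sel]
  here <- ent[ent$start >= min(st) & ent$end <= max(en), , drop = FALSE]
  here <- here[order(here$start), , drop = FALSE]
  owner <- rep(NA_integer_, length(sel))  # masking entity per token, if any
  for (k in seq_len(nrow(here))) {
    covered <- which(st >= here$start[k] & en <= here$end[k])
    owner[covered] <- k
  }
  out <- character(); pos <- integer(nrow(here))
  i <- 1L
  while (i <= length(sel)) {
    if (is.na(owner[i])) {
      out <- c(out, toks$surface[sel[i]])
      i <- i + 1L
    } else {
      k <- owner[i]
      out <- c(out, here$label[k])
      pos[k] <- length(out)
      while (i <= length(sel) && identical(owner[i], k)) i <- i + 1L
    }
  }
  list(tokens = out,
       triggerPos = pos[match(pair$trigger, here$id)],
       argumentPos = pos[match(pair$argument, here$id)])
}

candidateFeatures <- function(doc, pair) {
  m <- maskPair(doc, pair)
  ent <- entities(doc)
  trig <- ent[match(pair$trigger, ent$id), ]
  arg <- ent[match(pair$argument, ent$id), ]
  d <- abs(m$triggerPos - m$argumentPos)
  bin <- if (d <= 3L) as.character(d) else if (d <= 5L) "4-5" else
    if (d <= 8L) "6-8" else "9+"
  between <- if (d > 1L) {
    rng <- (min(m$triggerPos, m$argumentPos) + 1L):(max(m$triggerPos, m$argumentPos) - 1L)
    unique(paste0("bt=", tolower(m$tokens[rng])))
  } else character()
  unique(c(paste0("tok=", tolower(m$tokens)), between,
           paste0("trig=", tolower(trig$surface)),
           paste0("tl=", trig$label), paste0("al=", arg$label),
           paste0("dist=", bin),
           paste0("dir=", if (m$triggerPos < m$argumentPos) "t<a" else "t>a")))
}

#' RelationClassifier: binary accept/reject model over candidate pairs
#'
#' @slot backend backend name (default `"glmnet"`).
#' @slot fit the fitted model object.
#' @slot featureNames feature column order of the design matrix.
#' @slot threshold acceptance probability threshold.
#' @slot lambda regularization strength used at prediction time.
#' @slot seed integer seed.
#' @slot config training configuration list.
#' @exportClass RelationClassifier
setClass("RelationClassifier",
  representation(backend = "character", fit = "ANY",
                 featureNames = "character", threshold = "numeric",
                 lambda = "numeric", seed = "integer", config = "list"))

setValidity("RelationClassifier", function(object) {
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must lie in [0, 1]")
  TRUE
})

setMethod("show", "RelationClassifier", function(object) {
  cat(sprintf("RelationClassifier (%s): %d features, threshold %.2f\n",
              object@backend, length(object@featureNames), object@threshold))
})

#' Relation classifier configuration
#'
#' @param seed integer seed (recorded; the default backend is deterministic).
#' @param threshold acceptance probability threshold.
#' @param lambda ridge penalty used by the default backend.
#' @return a named list.
#' @export
relationConfig <- function(seed = 42L, threshold = 0.5, lambda = 1e-3) {
  list(seed = as.integer(seed), threshold = threshold, lambda = lambda)
}

candidateMatrix <- function(featList, featureNames) {
  index <- new.env(parent = emptyenv(), size = max(16L, length(featureNames)))
  for (j in seq_along(featureNames)) assign(featureNames[[j]], j, envir = index)
  ii <- integer(); jj <- integer()
  for (i in seq_along(featList)) {
    cols <- unlist(mget(featList[[i]], envir = index, ifnotfound = list(NULL)),
                   use.names = FALSE)
    ii <- c(ii, rep(i, length(cols)))
    jj <- c(jj, cols)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(length(featList), length(featureNames)))
}

#' Train the relation classifier
#'
#' Builds candidate pairs from the gold entities of the training documents;
#' positives are the annotated relations, negatives all remaining
#' candidates. The default backend is a ridge-regularized logistic
#' regression (glmnet) over bag-of-masked-tokens, trigger-surface,
#' argument-label and token-distance features; with a fixed penalty the fit
#' is deterministic.
#'
#' @param docs list of tokenized [Document-class] with gold entities and
#'   relations.
#' @param config see [relationConfig()].
#' @return a [RelationClassifier-class].
#' @export
trainRelationClassifier <- function(docs, config = relationConfig()) {
  featList <- list(); y <- logical()
  for (doc in docs) {
    if (!nrow(tokens(doc))) doc <- tokenizeDocument(doc)
    cand <- generateCandidates(doc)
    if (!nrow(cand)) next
    rel <- relations(doc)
    goldKey <- paste(rel$trigger, rel$argument, sep = "\r")
    for (i in seq_len(nrow(cand))) {
      featList[[length(featList) + 1L]] <- candidateFeatures(doc, cand[i, ])
      y <- c(y, paste(cand$trigger[i], cand$argument[i], sep = "\r") %in% goldKey)
    }
  }
  if (!length(featList)) stop("no candidate pairs in the training corpus")
  if (length(unique(y)) < 2L)
    stop("training candidates are single-class (all ",
         if (y[1L]) "positive" else "negative", "); cannot fit a classifier")
  featureNames <- sort(unique(unlist(featList)))
  X <- candidateMatrix(featList, featureNames)
  lam <- config$lambda
  fit <- glmnet::glmnet(X, factor(y, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = 0,
                        lambda = c(100 * lam, 10 * lam, lam),
                        standardize = FALSE)
  new("RelationClassifier", backend = "glmnet", fit = fit,
      featureNames = featureNames, threshold = config$threshold,
      lambda = lam, seed = config$seed, config = config)
}

#' Score candidate pairs of a document
#'
#' @param model a [RelationClassifier-class].
#' @param doc a tokenized [Document-class] with entities.
#' @return the candidate data.frame with a `score` column (acceptance
#'   probability).
#' @export
scoreCandidates <- function(model, doc) {
  cand <- generateCandidates(doc)
  if (!nrow(cand)) { cand$score <- numeric(); return(cand) }
  featList <- lapply(seq_len(nrow(cand)), function(i)
    candidateFeatures(doc, cand[i, ]))
  X <- candidateMatrix(featList, model@featureNames)
  cand$score <- as.numeric(stats::predict(model@fit, newx = X,
                                          s = model@lambda, type = "response"))
  cand
}

#' Predict relation mentions for a document
#'
#' Accepts candidates whose score reaches the model threshold and labels
#' them with [assignRelationLabel()] (ARG1 for compound arguments, ARGM for
#' time/temperature/yield arguments).
#'
#' @inheritParams scoreCandidates
#' @return relation data.frame with fresh `R<i>` ids.
#' @export
predictRelations <- function(model, doc) {
  cand <- scoreCandidates(model, doc)
  keep <- cand[cand$score >= model@threshold, , drop = FALSE]
  if (!nrow(keep)) return(emptyRelations())
  ent <- entities(doc)
  lab <- assignRelationLabel(ent$label[match(keep$trigger, ent$id)],
                             ent$label[match(keep$argument, ent$id)])
  data.frame(id = paste0("R", seq_len(nrow(keep))), label = lab,
             trigger = keep$trigger, argument = keep$argument,
             stringsAsFactors = FALSE)
}

#' Save / load a relation classifier
#'
#' @param model a [RelationClassifier-class].
#' @param path file path.
#' @export
saveRelationClassifier <- function(model, path) {
  saveRDS(list(format = "ChemPatentIE-relclf-v1", backend = model@backend,
               fit = model@fit, featureNames = model@featureNames,
               threshold = model@threshold, lambda = model@lambda,
               seed = model@seed, config = model@config), path, version = 3L)
  invisible(path)
}

#' @rdname saveRelationClassifier
#' @export
loadRelationClassifier <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "ChemPatentIE-relclf-v1"))
    stop("not a relation classifier file: ", path)
  new("RelationClassifier", backend = x$backend, fit = x$fit,
      featureNames = x$featureNames, threshold = x$threshold,
      lambda = x$lambda, seed = x$seed, config = x$config)
}
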