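# Joint sequence labeler for semantic roles and event triggers. The default
# backend is an averaged structured perceptron over surface features with
# first-order transitions and Viterbi decoding — a desk-scale linear-chain
# model. The backend is a contract (deterministic under seed, pure
# prediction), so heavier taggers can be plugged in behind the same surface.

#' TaggerModel: a trained sequence-labeling model
#'
#' @slot backend backend name (default `"perceptron"`).
#' @slot weights numeric matrix, features x tags (rownames are feature
#'   strings, sorted).
#' @slot transitions numeric matrix, (tags + initial row) x tags.
#' @slot labelSet the BIO tag strings the model emits.
#' @slot seed integer seed the model was trained under.
#' @slot config training configuration list.
#' @exportClass TaggerModel
setClass("TaggerModel",
  representation(backend = "character", weights = "matrix",
                 transitions = "matrix", labelSet = "character",
                 seed = "integer", config = "list"))

setMethod("show", "TaggerModel", function(object) {
  cat(sprintf("TaggerModel (%s): %d features, %d tags, seed %d\n",
              object@backend, nrow(object@weights), length(object@labelSet),
              object@seed))
})

#' Tagger training configuration
#'
#' @param seed RNG seed controlling the (deterministic) epoch shuffling.
#' @param epochs number of perceptron passes over the corpus.
#' @param window context window half-width for neighbor features.
#' @return a named list.
#' @export
taggerConfig <- function(seed = 42L, epochs = 5L, window = 2L) {
  list(seed = as.integer(seed), epochs = as.integer(epochs),
       window = as.integer(window))
}

tokenShape <- function(surface) {
  s <- gsub("[[:upper:]]", "X", surface)
  s <- gsub("[[:lower:]]", "x", s)
  s <- gsub("[0-9]", "d", s)
  # collapse runs so long names and numbers share a shape
  gsub("(.)\\1+", "\\1\\1", s)
}

isPunctToken <- function(surface) {
  nchar(surface) == 1L & !grepl("[\\p{L}\\p{N}]", surface, perl = TRUE)
}

# Feature strings for each position of one sentence.
sentenceFeatures <- function(surfaces, window = 2L) {
  n <- length(surfaces)
  low <- tolower(surfaces)
  shp <- tokenShape(surfaces)
  pun <- ifelse(isPunctToken(surfaces), "pn=1", "pn=0")
  pad <- function(v, k) {
    if (k < 0L) c(rep("<S>", -k), v[seq_len(max(0L, n + k))])
    else c(v[seq_len(n)][-seq_len(min(k, n))], rep("</S>", min(k, n)))
  }
  base <- list(paste0("w=", surfaces), paste0("lw=", low), paste0("sh=", shp),
               pun,
               paste0("p2=", substr(low, 1L, 2L)),
               paste0("p3=", substr(low, 1L, 3L)),
               paste0("s2=", substring(low, pmax(1L, nchar(low) - 1L))),
               paste0("s3=", substring(low, pmax(1L, nchar(low) - 2L))))
  for (k in seq_len(window)) {
    base[[length(base) + 1L]] <- paste0("lw-", k, "=", pad(low, -k))
    base[[length(base) + 1L]] <- paste0("lw+", k, "=", pad(low, k))
  }
  base[[length(base) + 1L]] <- paste0("sh-1=", pad(shp, -1L))
  base[[length(base) + 1L]] <- paste0("sh+1=", pad(shp, 1L))
  mat <- do.call(cbind, base)
  lapply(seq_len(n), function(i) mat[i, ])
}

# Emission score matrix (positions x tags) from an environment of weight
# vectors (training) or a weight matrix + rowname index (prediction).
scoreFromEnv <- function(feats, wEnv, K) {
  n <- length(feats)
  base <- matrix(0, n, K)
  for (i in seq_len(n)) {
    for (f in feats[[i]]) {
      v <- wEnv[[f]]
      if (!is.null(v)) base[i, ] <- base[i, ] + v
    }
  }
  base
}

scoreFromMatrix <- function(feats, W, index) {
  n <- length(feats)
  base <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    rows <- unlist(mget(feats[[i]], envir = index, ifnotfound = list(NULL)),
                   use.names = FALSE)
    if (length(rows) == 1L) base[i, ] <- W[rows, ]
    else if (length(rows) > 1L) base[i, ] <- colSums(W[rows, , drop = FALSE])
  }
  base
}

# First-order Viterbi. trans has K+1 rows; row K+1 scores the initial tag.
viterbiDecode <- function(base, trans) {
  n <- nrow(base); K <- ncol(base)
  if (n == 0L) return(integer())
  delta <- base[1L, ] + trans[K + 1L, ]
  back <- matrix(0L, n, K)
  if (n > 1L) {
    for (i in 2L:n) {
      M <- trans[seq_len(K), , drop = FALSE] + delta  # delta recycles down columns
      bp <- max.col(t(M), ties.method = "first")
      delta <- M[cbind(bp, seq_len(K))] + base[i, ]
      back[i, ] <- bp
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) for (i in n:2L) path[i - 1L] <- back[i, path[i]]
  path
}

#' Train the sequence tagger
#'
#' Averaged structured perceptron: for each sentence the current model
#' decodes a tag path by Viterbi; mispredicted positions and transitions
#' receive additive updates, and the final model averages the weights over
#' all updates, which stabilizes the perceptron. Training is deterministic
#' under `config$seed` (the seed drives the per-epoch sentence shuffling).
#'
#' @param docs list of tokenized [Document-class] with gold entities aligned
#'   to token boundaries.
#' @param config see [taggerConfig()].
#' @return a [TaggerModel-class] whose label set covers all labels seen.
#' @export
trainTagger <- function(docs, config = taggerConfig()) {
  if (!length(docs)) stop("cannot train a tagger on an empty corpus")
  tagset <- bioTagset()
  K <- length(tagset)
  sents <- list()
  for (doc in docs) {
    if (!nrow(tokens(doc))) doc <- tokenizeDocument(doc)
    tags <- encodeBio(tokens(doc), entities(doc))
    toks <- tokens(doc)
    for (s in unique(toks$sentence)) {
      sel <- toks$sentence == s
      sents[[length(sents) + 1L]] <- list(
        feats = sentenceFeatures(toks$surface[sel], config$window),
        gold = match(tags[sel], tagset))
    }
  }
  W <- new.env(parent = emptyenv())
  A <- new.env(parent = emptyenv())
  trans <- matrix(0, K + 1L, K)
  transA <- matrix(0, K + 1L, K)
  t <- 0L
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  bump <- function(env, key, delta) {
    v <- env[[key]]
    if (is.null(v)) v <- numeric(K)
    env[[key]] <- v + delta
  }
  for (epoch in seq_len(config$epochs)) {
    for (si in sample.int(length(sents))) {
      t <- t + 1L
      sent <- sents[[si]]
      n <- length(sent$gold)
      base <- scoreFromEnv(sent$feats, W, K)
      pred <- viterbiDecode(base, trans)
      if (identical(pred, sent$gold)) next
      for (i in seq_len(n)) {
        g <- sent$gold[i]; p <- pred[i]
        if (g != p) {
          for (f in sent$feats[[i]]) {
            d <- numeric(K); d[g] <- 1; d[p] <- -1
            bump(W, f, d)
            bump(A, f, t * d)
          }
        }
        pg <- if (i == 1L) K + 1L else sent$gold[i - 1L]
        pp <- if (i == 1L) K + 1L else pred[i - 1L]
        if (g != p || pg != pp) {
          trans[pg, g] <- trans[pg, g] + 1; transA[pg, g] <- transA[pg, g] + t
          trans[pp, p] <- trans[pp, p] - 1; transA[pp, p] <- transA[pp, p] - t
        }
      }
    }
  }
  keys <- ls(W, sorted = TRUE)
  Wm <- matrix(0, length(keys), K, dimnames = list(keys, tagset))
  for (j in seq_along(keys)) {
    a <- A[[keys[j]]]
    if (is.null(a)) a <- numeric(K)
    Wm[j, ] <- W[[keys[j]]] - a / t
  }
  transAvg <- trans - transA / t
  dimnames(transAvg) <- list(c(tagset, "<start>"), tagset)
  new("TaggerModel", backend = "perceptron", weights = Wm,
      transitions = transAvg, labelSet = tagset, seed = config$seed,
      config = config)
}

taggerIndex <- function(model) {
  keys <- rownames(model@weights)
  env <- new.env(parent = emptyenv(), size = max(16L, length(keys)))
  for (j in seq_along(keys)) assign(keys[[j]], j, envir = env)
  env
}

#' Predict entity mentions for a document
#'
#' Runs per-sentence Viterbi decoding and converts the tag paths back to
#' entity mentions with [decodeBio()]. Output spans are aligned to token
#' boundaries and never overlap.
#'
#' @param model a [TaggerModel-class].
#' @param doc a tokenized [Document-class].
#' @param index optional prebuilt feature index (see [predictCorpus()]).
#' @return entity data.frame with fresh `T<i>` ids.
#' @export
predictEntities <- function(model, doc, index = NULL) {
  toks <- tokens(doc)
  if (!nrow(toks)) {
    if (nzchar(trimws(docText(doc))))
      stop("document ", docId(doc), " is not tokenized")
    return(emptyEntities())
  }
  if (is.null(index)) index <- taggerIndex(model)
  tags <- character(nrow(toks))
  for (s in unique(toks$sentence)) {
    sel <- which(toks$sentence == s)
    feats <- sentenceFeatures(toks$surface[sel], model@config$window)
    base <- scoreFromMatrix(feats, model@weights, index)
    path <- viterbiDecode(base, model@transitions)
    tags[sel] <- model@labelSet[path]
  }
  ents <- decodeBio(toks, tags, text = docText(doc))
  if (!nrow(ents)) return(emptyEntities())
  ents <- ents[order(ents$start), , drop = FALSE]
  data.frame(id = paste0("T", seq_len(nrow(ents))), label = ents$label,
             start = ents$start, end = ents$end, surface = ents$surface,
             stringsAsFactors = FALSE)
}

#' @param docs list of tokenized documents.
#' @rdname predictEntities
#' @return `predictCorpus` returns the documents with predicted entities
#'   installed (building the feature index once).
#' @export
predictCorpus <- function(model, docs) {
  index <- taggerIndex(model)
  lapply(docs, function(d) {
    ent <- predictEntities(model, d, index = index)
    d@entities <- ent
    d@relations <- emptyRelations()
    d
  })
}

#' Majority-vote ensembling of entity predictions
#'
#' An entity, identified by its label and span, is kept iff it appears in
#' strictly more than `k/2` of the `k` prediction sets. Overlapping
#' survivors are resolved greedily: higher vote count first, ties by earlier
#' start, then by longer span.
#'
#' @param predictions list of `k` entity data.frames.
#' @param k number of prediction sets (checked against the list length).
#' @return entity data.frame with fresh ids, sorted by start.
#' @export
ensembleVote <- function(predictions, k = length(predictions)) {
  if (k != length(predictions) || k < 1L)
    stop("k must equal the number of prediction sets (>= 1)")
  all <- do.call(rbind, lapply(predictions, function(p)
    p[, c("label", "start", "end", "surface"), drop = FALSE]))
  if (is.null(all) || !nrow(all)) return(emptyEntities())
  key <- paste(all$label, all$start, all$end, sep = "\r")
  votes <- table(key)
  uniq <- all[!duplicated(key), , drop = FALSE]
  uniq$votes <- as.integer(votes[paste(uniq$label, uniq$start, uniq$end, sep = "\r")])
  uniq <- uniq[uniq$votes * 2L > k, , drop = FALSE]
  if (!nrow(uniq)) return(emptyEntities())
  uniq <- uniq[order(-uniq$votes, uniq$start, -(uniq$end - uniq$start)), , drop = FALSE]
  kept <- logical(nrow(uniq))
  for (i in seq_len(nrow(uniq))) {
    ok <- TRUE
    if (any(kept)) {
      prev <- uniq[kept, , drop = FALSE]
      if (any(uniq$start[i] < prev$end & prev$start < uniq$end[i])) ok <- FALSE
    }
    kept[i] <- ok
  }
  out <- uniq[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  data.frame(id = paste0("T", seq_len(nrow(out))), label = out$label,
             start = out$start, end = out$end, surface = out$surface,
             stringsAsFactors = FALSE)
}

#' Save / load a tagger model
#'
#' Single-file serialization with a format version tag.
#'
#' @param model a [TaggerModel-class].
#' @param path file path.
#' @export
saveTagger <- function(model, path) {
  saveRDS(list(format = "ChemPatentIE-tagger-v1", backend = model@backend,
               weights = model@weights, transitions = model@transitions,
               labelSet = model@labelSet, seed = model@seed,
               config = model@config), path, version = 3L)
  invisible(path)
}

#' @rdname saveTagger
#' @export
loadTagger <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "ChemPatentIE-tagger-v1"))
    stop("not a tagger model file: ", path)
  new("TaggerModel", backend = x$backend, weights = x$weights,
      transitions = x$transitions, labelSet = x$labelSet, seed = x$seed,
      config = x$config)
}
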