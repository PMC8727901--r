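# Independent oracles and small fixture builders used across the suite.

# Maximum-bipartite-matching oracle: exhaustive search over assignments of
# gold mentions to compatible predicted mentions, maximizing the number of
# matches. Independent of the greedy matcher under test.
bruteMatchTP <- function(gold, pred, mode) {
  compatible <- function(g, p) {
    if (gold$label[g] != pred$label[p]) return(FALSE)
    if (mode == "exact")
      gold$start[g] == pred$start[p] && gold$end[g] == pred$end[p]
    else
      min(gold$end[g], pred$end[p]) > max(gold$start[g], pred$start[p])
  }
  rec <- function(g, used) {
    if (g > nrow(gold)) return(0L)
    best <- rec(g + 1L, used)
    for (p in seq_len(nrow(pred))) {
      if (!used[p] && compatible(g, p)) {
        used2 <- used; used2[p] <- TRUE
        best <- max(best, 1L + rec(g + 1L, used2))
      }
    }
    best
  }
  rec(1L, logical(nrow(pred)))
}

# Random gold/pred mention sets: disjoint gold spans with generous gaps,
# predictions derived by small boundary perturbations, drops, label flips
# and trailing spurious mentions (the regime NER predictions live in).
randomMentionSets <- function(labels = c("TIME", "SOLVENT")) {
  nGold <- sample.int(8L, 1L)
  start <- 0L
  gold <- list()
  for (i in seq_len(nGold)) {
    len <- sample(3:6, 1L)
    gold[[i]] <- data.frame(label = sample(labels, 1L), start = start,
                            end = start + len, stringsAsFactors = FALSE)
    start <- start + len + sample(3:6, 1L)
  }
  gold <- do.call(rbind, gold)
  pred <- list()
  for (i in seq_len(nrow(gold))) {
    if (stats::runif(1L) > 0.8) next
    s <- gold$start[i] + sample(-2:2, 1L)
    e <- gold$end[i] + sample(-2:2, 1L)
    if (e <= s) e <- s + 1L
    lab <- if (stats::runif(1L) < 0.15) sample(labels, 1L) else gold$label[i]
    pred[[length(pred) + 1L]] <- data.frame(label = lab, start = max(0L, s),
                                            end = e, stringsAsFactors = FALSE)
  }
  nSpur <- sample(0:2, 1L)
  for (k in seq_len(nSpur)) {
    s <- start + 5L * k
    pred[[length(pred) + 1L]] <- data.frame(label = sample(labels, 1L),
                                            start = s, end = s + 3L,
                                            stringsAsFactors = FALSE)
  }
  list(gold = gold,
       pred = if (length(pred)) do.call(rbind, pred) else
         data.frame(label = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE))
}

# Majority-voting oracle: direct enumeration of the definition.
bruteMajorityKeys <- function(predictionKeys, k) {
  counts <- table(unlist(lapply(predictionKeys, unique)))
  keys <- names(counts)[as.integer(counts) > k / 2]
  if (is.null(keys)) character() else keys
}

# Raw relation/entity tables for the matching layer (not validated as a
# Document, so deliberately schema-violating labels can be probed).
relationTriplesFixture <- function(relLabel) {
  ent <- data.frame(id = c("T1", "T2"), label = c("REACTION_STEP", "TIME"),
                    start = c(0L, 11L), end = c(7L, 14L),
                    surface = c("stirred", "2 h"), stringsAsFactors = FALSE)
  rel <- data.frame(id = "R1", label = relLabel, trigger = "T1",
                    argument = "T2", stringsAsFactors = FALSE)
  list(rel = rel, ent = ent)
}

# A document whose annotations are exactly the given entity table.
docWithEntities <- function(text, ents, rels = NULL, id = "doc") {
  ents$id <- if (nrow(ents)) paste0("T", seq_len(nrow(ents))) else character()
  ents$surface <- if (nrow(ents))
    substring(text, ents$start + 1L, ents$end) else character()
  ents <- ents[, c("id", "label", "start", "end", "surface")]
  d <- Document(docId = id, text = text, entities = ents)
  if (!is.null(rels)) {
    rels$id <- paste0("R", seq_len(nrow(rels)))
    d@relations <- rels[, c("id", "label", "trigger", "argument")]
    validObject(d)
  }
  d
}
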