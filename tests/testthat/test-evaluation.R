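text40 <- paste(rep("x", 40), collapse = "")

entDf <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(label = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), stringsAsFactors = FALSE)))
}

test_that("precision, recall and F1 follow their defining ratios", {
  gold <- docWithEntities(text40, entDf(list("TIME", 0, 3), list("TIME", 5, 8),
                                        list("TIME", 10, 13)))
  pred <- docWithEntities(text40, entDf(list("TIME", 0, 3), list("TIME", 5, 8),
                                        list("TIME", 20, 23)))
  rep <- score(list(gold), list(pred), "ner", "exact")
  expect_equal(rep@overall$tp, 2L)
  expect_equal(rep@overall$fp, 1L)
  expect_equal(rep@overall$fn, 1L)
  expect_equal(rep@overall$precision, 2 / 3)
  expect_equal(rep@overall$recall, 2 / 3)
  expect_equal(rep@overall$f1, 2 / 3)
  # degenerate conventions
  none <- docWithEntities(text40, entDf(list("TIME", 0, 3))[0, ])
  rep0 <- score(list(gold), list(none), "ner", "exact")
  expect_equal(c(rep0@overall$precision, rep0@overall$recall, rep0@overall$f1),
               c(0, 0, 0))
  perfect <- score(list(gold), list(gold), "ner", "relaxed")
  expect_equal(perfect@overall$f1, 1)
})

test_that("exact needs identical spans, relaxed accepts overlap with equal label", {
  gold <- entDf(list("TIME", 0, 6))
  predOff <- entDf(list("TIME", 0, 5))
  exact <- matchEntities(gold, predOff, "exact")
  expect_equal(c(exact$tp, exact$fp, exact$fn), c(0L, 1L, 1L))
  relaxed <- matchEntities(gold, predOff, "relaxed")
  expect_equal(c(relaxed$tp, relaxed$fp, relaxed$fn), c(1L, 0L, 0L))
  # wrong label fails in both modes
  wrong <- entDf(list("SOLVENT", 0, 6))
  for (m in c("exact", "relaxed")) {
    res <- matchEntities(gold, wrong, m)
    expect_equal(sum(res$tp), 0L)
    expect_equal(sum(res$fp), 1L)
    expect_equal(sum(res$fn), 1L)
  }
})

relDocPair <- function(predShift = 0L, predLabel = "ARGM") {
  text <- "stirred at 50 ° C now"
  gold <- docWithEntities(text,
    entDf(list("REACTION_STEP", 0, 7), list("TEMPERATURE", 11, 17)),
    rels = data.frame(label = "ARGM", trigger = "T1", argument = "T2",
                      stringsAsFactors = FALSE))
  predEnts <- entDf(list("REACTION_STEP", 0, 7),
                    list("TEMPERATURE", 11, 17 + predShift))
  pred <- docWithEntities(text, predEnts,
    rels = data.frame(label = predLabel, trigger = "T1", argument = "T2",
                      stringsAsFactors = FALSE))
  list(gold = gold, pred = pred)
}

test_that("relation matching requires label equality and inherits the entity mode", {
  p <- relDocPair()
  expect_equal(score(list(p$gold), list(p$pred), "relation", "exact")@overall$f1, 1)
  # endpoint off by one character: exact fails, relaxed matches
  p <- relDocPair(predShift = 1L)
  expect_equal(score(list(p$gold), list(p$pred), "relation", "exact")@overall$tp, 0L)
  expect_equal(score(list(p$gold), list(p$pred), "relation", "relaxed")@overall$tp, 1L)
})

test_that("an ARG1/ARGM label mismatch is both a false positive and a false negative", {
  # same endpoints, wrong relation label (constructed at the matching layer,
  # since the document class would reject an ARG1 time argument)
  gold <- relationTriplesFixture("ARGM")
  pred <- relationTriplesFixture("ARG1")
  res <- matchRelations(gold$rel, pred$rel, gold$ent, pred$ent, "exact")
  expect_equal(sum(res$tp), 0L)
  expect_equal(sum(res$fp), 1L)
  expect_equal(sum(res$fn), 1L)
})

test_that("greedy matching agrees with the exhaustive matching oracle", {
  set.seed(2024)
  for (case in seq_len(200L)) {
    sets <- randomMentionSets()
    for (m in c("exact", "relaxed")) {
      got <- sum(matchEntities(sets$gold, sets$pred, m)$tp)
      expect_equal(got, bruteMatchTP(sets$gold, sets$pred, m),
                   info = sprintf("case %d mode %s", case, m))
    }
  }
})

test_that("relaxed F1 dominates exact F1 and order does not matter", {
  docs <- generateCorpus(generatorConfig(nDocuments = 10, seed = 33))
  set.seed(7)
  preds <- lapply(docs, function(d) {
    ent <- entities(d)
    keep <- stats::runif(nrow(ent)) < 0.8
    ent <- ent[keep, , drop = FALSE]
    # jitter some ends by one character (staying inside the text)
    jit <- stats::runif(nrow(ent)) < 0.3
    ent$end[jit] <- pmin(nchar(docText(d)), ent$end[jit] + 1L)
    ent$surface <- substring(docText(d), ent$start + 1L, ent$end)
    d@entities <- ent
    d@relations <- relations(d)[0, ]
    d
  })
  exact <- score(docs, preds, "ner", "exact")
  relaxed <- score(docs, preds, "ner", "relaxed")
  expect_gte(relaxed@overall$tp, exact@overall$tp)
  expect_gte(relaxed@overall$f1, exact@overall$f1)
  # permutation invariance in document order
  perm <- sample(length(docs))
  again <- score(docs[perm], preds[perm], "ner", "exact")
  expect_equal(again@overall, exact@overall)
  expect_equal(again@perLabel, exact@perLabel)
})

test_that("reports serialize to JSON with consistent rows", {
  docs <- generateCorpus(generatorConfig(nDocuments = 4, seed = 3))
  rep <- score(docs, docs, "ner", "exact")
  js <- jsonlite::fromJSON(reportJSON(rep))
  expect_equal(js$task, "ner")
  expect_true("Overall" %in% names(js$results))
  expect_equal(js$results$Overall$tp, sum(rep@perLabel$tp))
  expect_error(score(docs, docs[c(2, 1, 3)], "ner", "exact"), "one-to-one")
})
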