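triggerRoleDoc <- function() {
  # one sentence, 2 triggers, 3 roles; second sentence with a lone role
  text <- "NaH was added and stirred with THF and NH4Cl here. DMF waits."
  ents <- data.frame(
    label = c("REAGENT_CATALYST", "REACTION_STEP", "REACTION_STEP",
              "SOLVENT", "OTHER_COMPOUND", "SOLVENT"),
    start = c(0L, 8L, 18L, 31L, 39L, 51L),
    end = c(3L, 13L, 25L, 34L, 44L, 54L), stringsAsFactors = FALSE)
  tokenizeDocument(docWithEntities(text, ents))
}

test_that("candidates are the per-sentence trigger x role product", {
  doc <- triggerRoleDoc()
  cand <- generateCandidates(doc)
  expect_equal(nrow(cand), 6L)  # 2 triggers x 3 roles, sentence 2 has no trigger
  expect_true(all(cand$sentence == 1L))
  # roles without a trigger in their sentence yield nothing
  lone <- tokenizeDocument(docWithEntities("DMF waits.",
    data.frame(label = "SOLVENT", start = 0L, end = 3L, stringsAsFactors = FALSE)))
  expect_equal(nrow(generateCandidates(lone)), 0L)
})

test_that("EXAMPLE_LABEL is never a candidate argument", {
  text <- "Example 95 was stirred."
  ents <- data.frame(label = c("EXAMPLE_LABEL", "REACTION_STEP"),
                     start = c(8L, 15L), end = c(10L, 22L),
                     stringsAsFactors = FALSE)
  doc <- tokenizeDocument(docWithEntities(text, ents))
  expect_equal(nrow(generateCandidates(doc)), 0L)
})

test_that("candidate count matches the closed-form product over sentences", {
  docs <- generateCorpus(generatorConfig(nDocuments = 20, seed = 6))
  for (d in docs) {
    ent <- entities(d)
    si <- vapply(ent$start, function(s) {
      sen <- sentences(d)
      which(sen$start <= s & s < sen$end)[1L]
    }, integer(1L))
    expected <- sum(vapply(unique(si), function(s) {
      here <- ent[si == s, ]
      sum(isTrigger(here$label)) *
        sum(!isTrigger(here$label) & here$label != "EXAMPLE_LABEL")
    }, numeric(1L)))
    expect_equal(nrow(generateCandidates(d)), expected)
  }
})

test_that("masking replaces every mention run by its semantic type", {
  text <- "The mixture was stirred at 50 ° C"
  ents <- data.frame(label = c("REACTION_STEP", "TEMPERATURE"),
                     start = c(16L, 27L), end = c(23L, 33L),
                     stringsAsFactors = FALSE)
  doc <- tokenizeDocument(docWithEntities(text, ents))
  pair <- generateCandidates(doc)
  m <- maskPair(doc, pair[1, ])
  expect_equal(m$tokens,
               c("The", "mixture", "was", "REACTION_STEP", "at", "TEMPERATURE"))
  expect_equal(m$tokens[m$triggerPos], "REACTION_STEP")
  expect_equal(m$tokens[m$argumentPos], "TEMPERATURE")
  # all mentions are masked, so the masked sequence is shared across pairs
  doc2 <- triggerRoleDoc()
  cand <- generateCandidates(doc2)
  seqs <- lapply(seq_len(nrow(cand)), function(i) maskPair(doc2, cand[i, ])$tokens)
  expect_length(unique(seqs), 1L)
  expect_error(maskPair(doc2, list(sentence = 1L, trigger = "T99",
                                   argument = "T1")), "does not belong")
})

test_that("relation labels are determined by the argument role", {
  expect_equal(assignRelationLabel("REACTION_STEP", "SOLVENT"), "ARG1")
  expect_equal(assignRelationLabel("WORKUP", "TIME"), "ARGM")
  expect_equal(assignRelationLabel("REACTION_STEP", "YIELD_PERCENT"), "ARGM")
  # total on its domain: every trigger x role combination resolves
  for (t in triggerLabels())
    for (r in setdiff(roleLabels(), "EXAMPLE_LABEL"))
      expect_true(assignRelationLabel(t, r) %in% c("ARG1", "ARGM"))
  expect_error(assignRelationLabel("REACTION_STEP", "EXAMPLE_LABEL"),
               "EXAMPLE_LABEL")
  expect_error(assignRelationLabel("SOLVENT", "TIME"), "trigger")
})

test_that("the classifier separates templated positives from negatives", {
  docs <- generateCorpus(generatorConfig(nDocuments = 60, seed = 12))
  model <- trainRelationClassifier(docs)
  # training-set accuracy of the thresholded decision
  correct <- 0L; total <- 0L
  for (d in docs[1:20]) {
    cand <- scoreCandidates(model, d)
    rel <- relations(d)
    goldKey <- paste(rel$trigger, rel$argument)
    y <- paste(cand$trigger, cand$argument) %in% goldKey
    correct <- correct + sum((cand$score >= model@threshold) == y)
    total <- total + nrow(cand)
  }
  expect_gte(correct / total, 0.95)
})

test_that("classifier training is deterministic and degenerate cases error", {
  docs <- generateCorpus(generatorConfig(nDocuments = 12, seed = 19))
  m1 <- trainRelationClassifier(docs)
  m2 <- trainRelationClassifier(docs)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  saveRelationClassifier(m1, f1); saveRelationClassifier(m2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(loadRelationClassifier(f1)@featureNames, m1@featureNames)
  # threshold 0 accepts every candidate
  m0 <- m1; m0@threshold <- 0
  d <- docs[[1L]]
  expect_equal(nrow(predictRelations(m0, d)), nrow(generateCandidates(d)))
  # a single-class training set cannot be fit
  onlyPos <- docWithEntities("NaH was added.",
    data.frame(label = c("REAGENT_CATALYST", "REACTION_STEP"),
               start = c(0L, 8L), end = c(3L, 13L), stringsAsFactors = FALSE),
    rels = data.frame(label = "ARG1", trigger = "T2", argument = "T1",
                      stringsAsFactors = FALSE))
  expect_error(trainRelationClassifier(list(tokenizeDocument(onlyPos))),
               "single-class")
})

test_that("predicted relations satisfy the schema invariants", {
  docs <- generateCorpus(generatorConfig(nDocuments = 30, seed = 23))
  model <- trainRelationClassifier(docs[1:25])
  expect_equal(nrow(predictRelations(model,
    tokenizeDocument(docWithEntities("DMF waits.",
      data.frame(label = "SOLVENT", start = 0L, end = 3L,
                 stringsAsFactors = FALSE))))), 0L)
  valid <- expand.grid(label = c("ARG1", "ARGM"), trig = triggerLabels(),
                       stringsAsFactors = FALSE)
  for (d in docs[26:30]) {
    rel <- predictRelations(model, d)
    ent <- entities(d)
    if (!nrow(rel)) next
    tl <- ent$label[match(rel$trigger, ent$id)]
    al <- ent$label[match(rel$argument, ent$id)]
    expect_true(all(isTrigger(tl)))
    expect_identical(rel$label, unname(assignRelationLabel(tl, al)))
  }
})
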