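test_that("example-heading identifiers are trimmed to the bare identifier", {
  text <- "Example 95 and (Step 2) and 95"
  e <- function(start, end) {
    data.frame(id = "T1", label = "EXAMPLE_LABEL", start = start, end = end,
               surface = substring(text, start + 1L, end),
               stringsAsFactors = FALSE)
  }
  out <- trimExampleLabel(e(0L, 10L), text)   # "Example 95" -> "95"
  expect_equal(out$surface, "95")
  expect_equal(c(out$start, out$end), c(8L, 10L))
  out <- trimExampleLabel(e(15L, 23L), text)  # "(Step 2)" -> "2"
  expect_equal(out$surface, "2")
  out <- trimExampleLabel(e(28L, 30L), text)  # "95" unchanged
  expect_equal(out$surface, "95")
  expect_false(attr(out, "changed"))
  # trimming that would empty the span leaves the mention untouched
  text2 <- "Example"
  whole <- data.frame(id = "T1", label = "EXAMPLE_LABEL", start = 0L, end = 7L,
                      surface = "Example", stringsAsFactors = FALSE)
  out <- trimExampleLabel(whole, text2)
  expect_equal(out$surface, "Example")
  expect_true(attr(out, "warning"))
})

test_that("compound lead words are trimmed only from numeric identifiers", {
  text <- "compound 1-0003 or Example 56A or sodium chloride"
  e <- function(label, start, end) {
    data.frame(id = "T1", label = label, start = start, end = end,
               surface = substring(text, start + 1L, end),
               stringsAsFactors = FALSE)
  }
  out <- trimCompoundPrefix(e("OTHER_COMPOUND", 0L, 15L), text)
  expect_equal(out$surface, "1-0003")
  out <- trimCompoundPrefix(e("REACTION_PRODUCT", 19L, 30L), text)
  expect_equal(out$surface, "56A")
  out <- trimCompoundPrefix(e("OTHER_COMPOUND", 34L, 49L), text)
  expect_equal(out$surface, "sodium chloride")
  expect_false(attr(out, "changed"))
})

substepDoc <- function(topLabels = c("OTHER_COMPOUND", "OTHER_COMPOUND"),
                       subLabel = "REACTION_PRODUCT") {
  text <- "EXAMPLE 48\nNaH and THF\n48.1\nNH4Cl\nA solution was stirred."
  ents <- data.frame(
    label = c("EXAMPLE_LABEL", topLabels, subLabel),
    start = c(8L, 11L, 19L, 28L), end = c(10L, 14L, 22L, 33L),
    stringsAsFactors = FALSE)
  tokenizeDocument(docWithEntities(text, ents))
}

test_that("heading compounds are relabeled around a sub-step heading", {
  # mislabeled the way a context-free tagger would: product label up top,
  # other-compound label in the sub-step region
  doc <- substepDoc(topLabels = c("REACTION_PRODUCT", "OTHER_COMPOUND"),
                    subLabel = "OTHER_COMPOUND")
  out <- relabelHeadingCompounds(doc)
  lab <- entities(out)$label
  expect_equal(lab[2:3], c("OTHER_COMPOUND", "OTHER_COMPOUND"))
  expect_equal(lab[4], "REACTION_PRODUCT")
  expect_equal(nrow(ruleTraces(out)), 2L)
  # correctly labeled document is a fixed point
  ok <- substepDoc()
  expect_identical(entities(relabelHeadingCompounds(ok)), entities(ok))
  # no sub-step heading: unchanged
  plain <- tokenizeDocument(docWithEntities("EXAMPLE 48\nNaH was stirred.",
    data.frame(label = c("EXAMPLE_LABEL", "OTHER_COMPOUND"),
               start = c(8L, 11L), end = c(10L, 14L), stringsAsFactors = FALSE)))
  expect_identical(entities(relabelHeadingCompounds(plain)), entities(plain))
})

satAqSplitDoc <- function() {
  # simulate the faulty segmentation: force a sentence break inside the
  # "sat. aq. NH4Cl" clause, as an unguarded splitter would produce
  text <- "The residue was dissolved in EtOAc and washed with sat. aq. NH4Cl."
  ents <- data.frame(
    label = c("REACTION_STEP", "SOLVENT", "WORKUP", "OTHER_COMPOUND"),
    start = c(16L, 29L, 39L, 60L), end = c(25L, 34L, 45L, 65L),
    stringsAsFactors = FALSE)
  doc <- docWithEntities(text, ents)
  doc@sentences <- data.frame(start = c(0L, 60L), end = c(59L, 66L))
  toks <- rbind(tokenizePunct(substring(text, 1L, 59L), 0L),
                tokenizePunct(substring(text, 61L, 66L), 60L))
  toks$sentence <- ifelse(toks$start < 60L, 1L, 2L)
  doc@tokens <- toks
  validObject(doc)
  doc
}

test_that("sat. aq. splits are merged and the chemical linked to a trigger", {
  doc <- satAqSplitDoc()
  out <- mergeSatAqAndLink(doc)
  expect_equal(nrow(sentences(out)), 1L)
  expect_equal(max(tokens(out)$sentence), 1L)
  rel <- relations(out)
  expect_equal(nrow(rel), 1L)
  ent <- entities(out)
  expect_equal(ent$surface[match(rel$argument, ent$id)], "NH4Cl")
  # nearest strategy picks "washed"; clause-head picks "dissolved"
  expect_equal(ent$surface[match(rel$trigger, ent$id)], "washed")
  alt <- relations(mergeSatAqAndLink(doc, strategy = "clause-head"))
  expect_equal(ent$surface[match(alt$trigger, ent$id)], "dissolved")
  # documents without the phenomenon are untouched
  other <- tokenizeDocument(docWithEntities("NaH was added.",
    data.frame(label = c("REAGENT_CATALYST", "REACTION_STEP"),
               start = c(0L, 8L), end = c(3L, 13L), stringsAsFactors = FALSE)))
  expect_identical(sentences(mergeSatAqAndLink(other)), sentences(other))
  expect_equal(nrow(relations(mergeSatAqAndLink(other))), 0L)
})

test_that("a guarded one-sentence sat. aq. clause still gets the missing link", {
  text <- "The residue was dissolved in EtOAc and washed with sat. aq. NH4Cl."
  ents <- data.frame(
    label = c("REACTION_STEP", "SOLVENT", "WORKUP", "OTHER_COMPOUND"),
    start = c(16L, 29L, 39L, 60L), end = c(25L, 34L, 45L, 65L),
    stringsAsFactors = FALSE)
  doc <- tokenizeDocument(docWithEntities(text, ents))
  expect_equal(nrow(sentences(doc)), 1L)  # the guard kept the clause whole
  out <- mergeSatAqAndLink(doc)
  expect_equal(nrow(relations(out)), 1L)
  # idempotent: the link is not duplicated
  out2 <- mergeSatAqAndLink(out)
  expect_identical(relations(out2), relations(out))
})

yieldDoc <- function(withTrigger = TRUE, yieldFirst = FALSE) {
  head <- if (withTrigger)
    "The mixture is purified by RP-HPLC (modifier: ammonium hydroxide). "
  else "The mixture is ready. "
  text <- paste0(if (!yieldFirst) head, "Yield: 15 mg (25% of theory).")
  off <- if (yieldFirst) 0L else nchar(head)
  ents <- data.frame(label = c("YIELD_OTHER", "YIELD_PERCENT"),
                     start = off + c(7L, 14L), end = off + c(12L, 17L),
                     stringsAsFactors = FALSE)
  if (withTrigger && !yieldFirst)
    ents <- rbind(data.frame(label = "WORKUP", start = 15L, end = 23L,
                             stringsAsFactors = FALSE), ents)
  tokenizeDocument(docWithEntities(text, ents))
}

test_that("standalone yield sentences link ARGM to the previous trigger", {
  doc <- yieldDoc()
  out <- linkYieldSentence(doc)
  rel <- relations(out)
  ent <- entities(out)
  expect_equal(nrow(rel), 2L)
  expect_true(all(rel$label == "ARGM"))
  expect_true(all(ent$surface[match(rel$trigger, ent$id)] == "purified"))
  expect_setequal(ent$surface[match(rel$argument, ent$id)], c("15 mg", "25%"))
  # no trigger in the previous sentence: warning trace, no relation
  noTrig <- linkYieldSentence(yieldDoc(withTrigger = FALSE))
  expect_equal(nrow(relations(noTrig)), 0L)
  expect_match(ruleTraces(noTrig)$after, "no trigger")
  # yield sentence opening the document: skipped with a trace
  first <- linkYieldSentence(yieldDoc(yieldFirst = TRUE))
  expect_equal(nrow(relations(first)), 0L)
  expect_match(ruleTraces(first)$after, "no previous sentence")
})

test_that("the full rule set is idempotent and only ever shrinks spans", {
  docs <- generateCorpus(generatorConfig(nDocuments = 15, seed = 27))
  for (d in docs) {
    once <- applyRelationRules(applyNerRules(d))
    twice <- applyRelationRules(applyNerRules(once))
    expect_identical(entities(twice), entities(once))
    expect_identical(relations(twice), relations(once))
    expect_identical(sentences(twice), sentences(once))
    before <- entities(d); after <- entities(once)
    common <- intersect(before$id, after$id)
    expect_true(all(after$start[match(common, after$id)] >=
                    before$start[match(common, before$id)]))
    expect_true(all(after$end[match(common, after$id)] <=
                    before$end[match(common, before$id)]))
  }
})

test_that("rule traces are emitted and serializable", {
  doc <- substepDoc(topLabels = c("REACTION_PRODUCT", "OTHER_COMPOUND"),
                    subLabel = "OTHER_COMPOUND")
  out <- relabelHeadingCompounds(doc)
  lines <- writeRuleTraces(out, withr::local_tempfile())
  expect_length(lines, 2L)
  expect_match(lines[1], "^relabel_heading_compounds\t")
})
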