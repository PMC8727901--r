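test_that("sentence segmentation splits on terminators with an abbreviation guard", {
  s <- segmentSentences("A solution was stirred. The mixture was filtered.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$start, c(0L, 24L))
  expect_equal(nrow(segmentSentences("")), 0L)
  expect_equal(nrow(segmentSentences("   \n  ")), 0L)
  # "sat." and "aq." stay sentence-internal
  txt <- "the residue was dissolved in EtOAc and washed with sat. aq. NH4Cl"
  s <- segmentSentences(txt)
  expect_equal(nrow(s), 1L)
  expect_equal(s$end, nchar(txt))
  # newlines terminate
  expect_equal(nrow(segmentSentences("EXAMPLE 48\nA solution was stirred.")), 2L)
})

test_that("every punctuation character separates tokens", {
  s <- "7-Bromo-4-(pyridin-2-yl)-3,4-dihydro-2H-benzo(b) (1,4)oxazine (1)"
  expect_equal(tokenizePunct(s)$surface,
               c("7", "-", "Bromo", "-", "4", "-", "(", "pyridin", "-", "2",
                 "-", "yl", ")", "-", "3", ",", "4", "-", "dihydro", "-",
                 "2H", "-", "benzo", "(", "b", ")", "(", "1", ",", "4", ")",
                 "oxazine", "(", "1", ")"))
  expect_equal(tokenizePunct("water")$surface, "water")
  expect_equal(tokenizePunct("6.5 mg")$surface, c("6", ".", "5", "mg"))
  expect_equal(tokenizePunct("2%")$surface, c("2", "%"))
  expect_equal(nrow(tokenizePunct("   ")), 0L)
})

test_that("tokenization is lossless, idempotent, offset-correct and punctuation-clean", {
  docs <- generateCorpus(generatorConfig(nDocuments = 15, seed = 9))
  for (d in docs) {
    toks <- tokens(d)
    # offsets verified against the text
    expect_identical(substring(docText(d), toks$start + 1L, toks$end),
                     toks$surface)
    for (i in seq_len(nrow(sentences(d)))) {
      sen <- sentences(d)[i, ]
      st <- toks[toks$sentence == i, , drop = FALSE]
      # lossless: surfaces plus skipped whitespace rebuild the sentence
      rebuilt <- ""
      cursor <- sen$start
      for (k in seq_len(nrow(st))) {
        rebuilt <- paste0(rebuilt,
                          substring(docText(d), cursor + 1L, st$start[k]),
                          st$surface[k])
        cursor <- st$end[k]
      }
      expect_identical(rebuilt,
                       substring(docText(d), sen$start + 1L, sen$end))
    }
    # idempotence and the punctuation dichotomy
    for (surface in unique(toks$surface)) {
      expect_identical(tokenizePunct(surface)$surface, surface)
      expect_true(nchar(surface) == 1L ||
                  !grepl("[^\\p{L}\\p{N}]", surface, perl = TRUE))
    }
  }
})

test_that("greedy longest-prefix subword alignment follows the vocabulary", {
  v <- new("SubwordVocabulary", entries = c("unable", "un", "##able"))
  expect_equal(subwordAlign("unable", v), "unable")
  v <- new("SubwordVocabulary", entries = c("un", "##able"))
  expect_equal(subwordAlign("unable", v), c("un", "##able"))
  expect_equal(subwordAlign("qzx", v), "[UNK]")
  # longest-prefix-first, not shortest
  v <- new("SubwordVocabulary", entries = c("a", "ab", "##c", "##bc"))
  expect_equal(subwordAlign("abc", v), c("ab", "##c"))
})

test_that("a built vocabulary decomposes any in-corpus token without unknowns", {
  docs <- generateCorpus(generatorConfig(nDocuments = 10, seed = 13))
  vocab <- buildVocabulary(docs, maxSize = 800L)
  idx <- ChemPatentIE:::vocabIndex(vocab)
  for (d in docs[1:5]) {
    for (surface in unique(tokens(d)$surface)) {
      pieces <- subwordAlign(surface, vocab, idx)
      expect_false(identical(pieces, vocab@unknownMarker))
      expect_identical(paste(sub("^##", "", pieces), collapse = ""), surface)
    }
  }
  # deterministic under identical inputs
  expect_identical(vocab@entries, buildVocabulary(docs, maxSize = 800L)@entries)
  expect_error(buildVocabulary(list(), 100L), "empty corpus")
  expect_error(buildVocabulary(docs, maxSize = 2L), "alphabet")
})

test_that("vocabulary files round-trip", {
  docs <- generateCorpus(generatorConfig(nDocuments = 5, seed = 2))
  vocab <- buildVocabulary(docs, maxSize = 300L)
  path <- withr::local_tempfile()
  writeVocabulary(vocab, path)
  back <- readVocabulary(path)
  expect_identical(back@entries, vocab@entries)
  expect_identical(back@unknownMarker, vocab@unknownMarker)
})
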