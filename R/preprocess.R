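# Sentence segmentation and the two-stage tokenization: a pass that treats
# every punctuation character as a token separator, then greedy
# vocabulary-driven subword alignment.

# Abbreviations whose trailing period must not end a sentence. "sat." and
# "aq." matter most: splitting "sat. aq. NH4Cl" severs the clause that links
# a workup trigger to the chemical that follows.
sentenceAbbreviations <- function() {
  c("sat.", "aq.", "approx.", "conc.", "vs.", "e.g.", "i.e.", "no.", "fig.")
}

#' Segment text into sentence spans
#'
#' Rule-based segmentation: `.`, `!`, `?` followed by whitespace or
#' end-of-text terminate a sentence, as do newlines, except that a period
#' closing a guarded abbreviation (e.g. "sat.", "aq.") is kept internal.
#' Returned spans are 0-based half-open, cover every non-whitespace
#' character, and are sorted and non-overlapping.
#'
#' @param text character scalar.
#' @return data.frame with columns `start`, `end`.
#' @examples
#' segmentSentences("A solution was stirred. The mixture was filtered.")
#' @export
segmentSentences <- function(text) {
  if (!nzchar(trimws(text))) return(emptySpans())
  m <- gregexpr("[.!?](?=\\s|$)|\n", text, perl = TRUE)[[1L]]
  breaks <- integer()  # 1-based position of the last character of a sentence
  if (m[1L] != -1L) {
    guard <- sentenceAbbreviations()
    for (p in as.integer(m)) {
      ch <- substr(text, p, p)
      if (ch == "\n") { breaks <- c(breaks, p - 1L); next }
      head <- substr(text, 1L, p)
      word <- sub("^.*\\s", "", head)  # maximal non-space run ending at p
      if (tolower(word) %in% guard) next
      breaks <- c(breaks, p)
    }
  }
  bounds <- unique(sort(c(breaks, nchar(text))))
  start1 <- 1L
  spans <- list()
  for (b in bounds) {
    if (b < start1) { start1 <- b + 1L; next }
    seg <- substr(text, start1, b)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    if (lead + trail < nchar(seg))
      spans[[length(spans) + 1L]] <- c(start1 + lead - 1L, b - trail)
    start1 <- b + 1L
  }
  if (!length(spans)) return(emptySpans())
  out <- do.call(rbind, spans)
  data.frame(start = as.integer(out[, 1L]), end = as.integer(out[, 2L]))
}

#' Punctuation-separator tokenization
#'
#' Splits a sentence into maximal alphanumeric runs and single-character
#' punctuation tokens: every non-alphanumeric, non-whitespace code point is
#' its own token. This keeps long chemical-name strings and numeric
#' expressions ("6.5 mg", "2%") tokenized consistently, which is what the
#' downstream sequence labeler relies on for boundary detection.
#'
#' @param text one sentence.
#' @param offset 0-based document offset of the sentence start.
#' @return token data.frame (`surface`, `start`, `end`, `sentence = NA`).
#' @examples
#' tokenizePunct("6.5 mg")$surface  # "6" "." "5" "mg"
#' @export
tokenizePunct <- function(text, offset = 0L) {
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(emptyTokens())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(surface = substring(text, starts, starts + lens - 1L),
             start = offset + starts - 1L, end = offset + starts + lens - 1L,
             sentence = NA_integer_, stringsAsFactors = FALSE)
}

#' Segment and tokenize a document in place
#'
#' Fills the `sentences` and `tokens` slots from the raw text using
#' [segmentSentences()] and [tokenizePunct()].
#'
#' @param doc a [Document-class].
#' @return the document with sentence and token tables populated.
#' @export
tokenizeDocument <- function(doc) {
  sen <- segmentSentences(docText(doc))
  doc@sentences <- sen
  toks <- lapply(seq_len(nrow(sen)), function(i) {
    t <- tokenizePunct(substrCP(docText(doc), sen$start[i], sen$end[i]),
                       offset = sen$start[i])
    if (nrow(t)) t$sentence <- i
    t
  })
  doc@tokens <- if (length(toks)) do.call(rbind, toks) else emptyTokens()
  rownames(doc@tokens) <- NULL
  validObject(doc)
  doc
}

# --- subword vocabulary ----------------------------------------------------

#' SubwordVocabulary: word pieces for the second tokenization stage
#'
#' Holds initial pieces and continuation pieces (prefixed `##`) plus an
#' unknown marker. Drives the greedy longest-prefix-first decomposition of
#' [subwordAlign()].
#'
#' @slot entries character vector of pieces.
#' @slot unknownMarker marker emitted when no decomposition exists.
#' @exportClass SubwordVocabulary
setClass("SubwordVocabulary",
  representation(entries = "character", unknownMarker = "character"),
  prototype(entries = character(), unknownMarker = "[UNK]"))

setValidity("SubwordVocabulary", function(object) {
  if (object@unknownMarker %in% object@entries)
    return("unknown marker must not be a vocabulary entry")
  TRUE
})

setMethod("show", "SubwordVocabulary", function(object) {
  cat(sprintf("SubwordVocabulary: %d pieces (%d continuation), unknown = %s\n",
              length(object@entries),
              sum(startsWith(object@entries, "##")), object@unknownMarker))
})

vocabIndex <- function(vocab) {
  env <- new.env(parent = emptyenv(), size = max(16L, length(vocab@entries)))
  for (e in vocab@entries) assign(e, TRUE, envir = env)
  env
}

#' Greedy subword decomposition of a token
#'
#' Repeatedly takes the longest vocabulary piece matching the remaining
#' suffix (continuation pieces, `##`-prefixed, after the first piece). If at
#' any step no piece matches, the whole token maps to the unknown marker.
#'
#' @param surface token surface string.
#' @param vocab a [SubwordVocabulary-class].
#' @param index optional prebuilt lookup environment (from repeated calls).
#' @return character vector of pieces, or the unknown marker.
#' @examples
#' v <- new("SubwordVocabulary", entries = c("un", "##able"))
#' subwordAlign("unable", v)  # "un" "##able"
#' @export
subwordAlign <- function(surface, vocab, index = NULL) {
  if (is.null(index)) index <- vocabIndex(vocab)
  n <- nchar(surface)
  pos <- 1L
  pieces <- character()
  while (pos <= n) {
    found <- FALSE
    for (len in seq.int(n - pos + 1L, 1L)) {
      piece <- substr(surface, pos, pos + len - 1L)
      key <- if (pos == 1L) piece else paste0("##", piece)
      if (!is.null(index[[key]])) {
        pieces <- c(pieces, key)
        pos <- pos + len
        found <- TRUE
        break
      }
    }
    if (!found) return(vocab@unknownMarker)
  }
  pieces
}

#' Build a subword vocabulary from a corpus
#'
#' Frequency-ranked character n-gram pieces: every single character observed
#' in the corpus enters the vocabulary (in both initial and continuation
#' form), guaranteeing that no in-corpus token maps to the unknown marker;
#' the remaining budget up to `maxSize` is filled with the most frequent
#' longer pieces (ties broken lexicographically, so the build is
#' deterministic).
#'
#' @param docs list of [Document-class] (tokenized on the fly if needed).
#' @param maxSize maximum number of vocabulary entries; must be at least the
#'   size of the observed character alphabet.
#' @param maxPiece longest piece length considered.
#' @return a [SubwordVocabulary-class].
#' @export
buildVocabulary <- function(docs, maxSize = 2000L, maxPiece = 8L) {
  if (!length(docs)) stop("cannot build a vocabulary from an empty corpus")
  surf <- unlist(lapply(docs, function(d) {
    if (!nrow(tokens(d))) d <- tokenizeDocument(d)
    tokens(d)$surface
  }))
  counts <- table(surf)
  words <- names(counts)
  nw <- as.integer(counts)
  chars <- unique(unlist(strsplit(words, "", fixed = TRUE)))
  alphabet <- sort(c(chars, paste0("##", chars)))
  if (maxSize < length(alphabet))
    stop("maxSize (", maxSize, ") is below the alphabet size (", length(alphabet), ")")
  grams <- new.env(parent = emptyenv())
  for (w in seq_along(words)) {
    word <- words[[w]]
    n <- nchar(word)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (len in 2L:min(maxPiece, n - i + 1L)) {
        piece <- substr(word, i, i + len - 1L)
        key <- if (i == 1L) piece else paste0("##", piece)
        grams[[key]] <- (if (is.null(grams[[key]])) 0L else grams[[key]]) + nw[[w]]
      }
    }
  }
  keys <- ls(grams, sorted = TRUE)
  keys <- setdiff(keys, alphabet)
  if (length(keys)) {
    freq <- vapply(keys, function(k) grams[[k]], integer(1L))
    ord <- order(-freq, keys)
    keep <- keys[ord][seq_len(min(length(keys), maxSize - length(alphabet)))]
  } else keep <- character()
  new("SubwordVocabulary", entries = sort(c(alphabet, keep)), unknownMarker = "[UNK]")
}

#' Attach subword decompositions to a document's tokens
#'
#' @param doc tokenized [Document-class].
#' @param vocab a [SubwordVocabulary-class].
#' @return the document with a `subwords` list column on its token table.
#' @export
alignSubwords <- function(doc, vocab) {
  idx <- vocabIndex(vocab)
  toks <- tokens(doc)
  toks$subwords <- I(lapply(toks$surface, subwordAlign, vocab = vocab, index = idx))
  doc@tokens <- toks
  doc
}

#' Read / write a subword vocabulary file
#'
#' Plain-text format: the first line is the unknown marker, then one piece
#' per line (continuation pieces carry the `##` prefix).
#'
#' @param path file path.
#' @export
readVocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty vocabulary file: ", path)
  new("SubwordVocabulary", unknownMarker = lines[[1L]], entries = lines[-1L])
}

#' @param vocab a [SubwordVocabulary-class].
#' @rdname readVocabulary
#' @export
writeVocabulary <- function(vocab, path) {
  writeLines(c(vocab@unknownMarker, vocab@entries), path, useBytes = FALSE)
  invisible(path)
}
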