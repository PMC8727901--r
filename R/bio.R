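# BIO span encoding over punctuation-level tokens. One joint tag set covers
# the 10 semantic roles and the 2 event-trigger types, so a single sequence
# model recognizes roles and triggers together.

#' The BIO tag set over the 12 entity labels
#'
#' @return character vector: `"O"` plus `B-`/`I-` forms of each label.
#' @export
bioTagset <- function() {
  c("O", as.vector(rbind(paste0("B-", entityLabels()),
                         paste0("I-", entityLabels()))))
}

#' Encode aligned entity mentions as per-token BIO tags
#'
#' Each entity span must coincide with a consecutive run of tokens; the first
#' token receives `B-<LABEL>`, the rest `I-<LABEL>`. Misaligned or
#' overlapping entities raise an alignment error naming the offending mention
#' — with the punctuation-separator tokenizer a misalignment indicates a
#' tokenization bug, so it fails loudly rather than snapping silently.
#'
#' @param tokens token data.frame (`surface`, `start`, `end`).
#' @param entities entity data.frame (`label`, `start`, `end`; `id` used in
#'   error messages when present).
#' @return character vector of tags, one per token.
#' @export
encodeBio <- function(tokens, entities) {
  tags <- rep("O", nrow(tokens))
  if (!nrow(entities)) return(tags)
  for (k in seq_len(nrow(entities))) {
    e <- entities[k, ]
    ident <- if (!is.null(e$id)) e$id else sprintf("[%d,%d)", e$start, e$end)
    i1 <- which(tokens$start == e$start)
    i2 <- which(tokens$end == e$end)
    if (length(i1) != 1L || length(i2) != 1L || i1 > i2 ||
        any(tokens$start[i1:i2] < e$start) || any(tokens$end[i1:i2] > e$end))
      stop("entity ", ident, " (", e$label, ") is not aligned to token boundaries")
    if (any(tags[i1:i2] != "O"))
      stop("entity ", ident, " overlaps a previously encoded entity")
    tags[i1:i2] <- c(paste0("B-", e$label),
                     rep(paste0("I-", e$label), i2 - i1))
  }
  tags
}

#' Decode per-token BIO tags into entity mentions
#'
#' Maximal `B`/`I` runs become entities. Decoding is lenient: an `I-` tag
#' following `O`, following a different label, or opening a sentence is
#' repaired as `B-`. Runs never cross sentence boundaries. For any validly
#' encoded entity set, `decodeBio(tokens, encodeBio(tokens, E))` reproduces
#' `E`.
#'
#' @param tokens token data.frame (with a `sentence` column when decoding a
#'   whole document).
#' @param tags character vector of BIO tags, one per token.
#' @param text optional document text used to fill entity surfaces.
#' @return entity data.frame (`label`, `start`, `end`, `surface`).
#' @export
decodeBio <- function(tokens, tags, text = NULL) {
  if (length(tags) != nrow(tokens))
    stop("length(tags) must equal the number of tokens (",
         length(tags), " vs ", nrow(tokens), ")")
  out <- list()
  open <- NULL  # c(firstToken, label)
  openLabel <- NA_character_
  openFirst <- NA_integer_
  sen <- if ("sentence" %in% names(tokens)) tokens$sentence else rep(1L, nrow(tokens))
  flush <- function(last) {
    if (is.na(openFirst)) return()
    out[[length(out) + 1L]] <<- data.frame(
      label = openLabel, start = tokens$start[openFirst],
      end = tokens$end[last], stringsAsFactors = FALSE)
    openFirst <<- NA_integer_
  }
  for (i in seq_along(tags)) {
    tag <- tags[[i]]
    newSentence <- i > 1L && !identical(sen[[i]], sen[[i - 1L]])
    if (tag == "O") { flush(i - 1L); next }
    prefix <- substr(tag, 1L, 1L)
    label <- substr(tag, 3L, nchar(tag))
    continues <- prefix == "I" && !is.na(openFirst) &&
      identical(label, openLabel) && !newSentence
    if (!continues) {
      flush(i - 1L)
      openFirst <- i
      openLabel <- label
    }
  }
  flush(length(tags))
  if (!length(out))
    return(cbind(emptyEntities()[, c("label", "start", "end")],
                 data.frame(surface = character())))
  ents <- do.call(rbind, out)
  ents$surface <- if (is.null(text)) NA_character_ else
    substrCP(text, ents$start, ents$end)
  ents
}
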