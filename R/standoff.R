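#' Read a snippet with BRAT-style standoff annotations
#'
#' Parses entity lines (`T<i><TAB>LABEL start end<TAB>surface`) and relation
#' lines (`R<i><TAB>LABEL Arg1:T<j> Arg2:T<k>`). The `Arg1:` slot of a
#' relation line names the event trigger, the `Arg2:` slot the role argument.
#' Offsets are 0-based half-open code-point positions. The legacy trigger
#' spellings `REACTION_SETUP` and `WORK_UP` are accepted and normalized to
#' `REACTION_STEP` / `WORKUP`. Discontinuous spans (offset lists with `;`)
#' are rejected: the scheme uses contiguous spans only.
#'
#' @param text snippet text.
#' @param ann standoff annotation text (possibly empty).
#' @param docId document identifier.
#' @return a [Document-class] with entities and relations materialized.
#' @examples
#' d <- readDocument("NH4Cl was added.", "T1\tOTHER_COMPOUND 0 5\tNH4Cl")
#' entities(d)
#' @export
readDocument <- function(text, ann, docId = "doc") {
  lines <- if (nzchar(ann)) strsplit(ann, "\n", fixed = TRUE)[[1L]] else character()
  lines <- lines[nzchar(trimws(lines))]
  ents <- list(); rels <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    kind <- substr(fields[[1L]], 1L, 1L)
    if (kind == "T") {
      if (length(fields) < 3L)
        stop("line ", i, ": malformed entity line (expected id, 'LABEL start end', surface)")
      spec <- strsplit(fields[[2L]], " ", fixed = TRUE)[[1L]]
      if (grepl(";", fields[[2L]], fixed = TRUE))
        stop("line ", i, ": discontinuous spans are not supported")
      if (length(spec) != 3L || is.na(suppressWarnings(as.integer(spec[[2L]]))) ||
          is.na(suppressWarnings(as.integer(spec[[3L]]))))
        stop("line ", i, ": malformed entity span specification ", dQuote(fields[[2L]]))
      label <- normalizeLabel(spec[[1L]])
      if (!label %in% entityLabels())
        stop("line ", i, ": unknown entity label ", dQuote(spec[[1L]]))
      start <- as.integer(spec[[2L]]); end <- as.integer(spec[[3L]])
      if (start < 0L || end > nchar(text) || start >= end)
        stop("line ", i, ": offsets [", start, ",", end, ") out of bounds for text of length ",
             nchar(text))
      surface <- paste(fields[-(1:2)], collapse = "\t")
      if (surface != substrCP(text, start, end))
        stop("line ", i, ": surface ", dQuote(surface),
             " does not match text substring ", dQuote(substrCP(text, start, end)))
      ents[[length(ents) + 1L]] <- data.frame(
        id = fields[[1L]], label = label, start = start, end = end,
        surface = surface, stringsAsFactors = FALSE)
    } else if (kind == "R") {
      if (length(fields) < 2L)
        stop("line ", i, ": malformed relation line")
      spec <- strsplit(fields[[2L]], " ", fixed = TRUE)[[1L]]
      if (length(spec) != 3L || !grepl("^Arg1:", spec[[2L]]) || !grepl("^Arg2:", spec[[3L]]))
        stop("line ", i, ": malformed relation specification ", dQuote(fields[[2L]]))
      if (!spec[[1L]] %in% c("ARG1", "ARGM"))
        stop("line ", i, ": unknown relation label ", dQuote(spec[[1L]]))
      rels[[length(rels) + 1L]] <- data.frame(
        id = fields[[1L]], label = spec[[1L]],
        trigger = sub("^Arg1:", "", spec[[2L]]),
        argument = sub("^Arg2:", "", spec[[3L]]), stringsAsFactors = FALSE)
    } else {
      stop("line ", i, ": unsupported record type ", dQuote(fields[[1L]]))
    }
  }
  Document(docId = docId, text = text,
           entities = if (length(ents)) do.call(rbind, ents) else emptyEntities(),
           relations = if (length(rels)) do.call(rbind, rels) else emptyRelations())
}

#' Serialize a document's annotations to standoff text
#'
#' Inverse of [readDocument()]: `readDocument(docText(d), writeAnnotations(d))`
#' reproduces the entity and relation sets exactly.
#'
#' @param doc a valid [Document-class].
#' @return standoff annotation text, newline-terminated records ("" if the
#'   document carries no annotations).
#' @export
writeAnnotations <- function(doc) {
  validObject(doc)
  ent <- entities(doc); rel <- relations(doc)
  lines <- character()
  if (nrow(ent))
    lines <- c(lines, sprintf("%s\t%s %d %d\t%s", ent$id, ent$label,
                              ent$start, ent$end, ent$surface))
  if (nrow(rel))
    lines <- c(lines, sprintf("%s\t%s Arg1:%s Arg2:%s", rel$id, rel$label,
                              rel$trigger, rel$argument))
  if (!length(lines)) return("")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read / write corpora as <id>.txt / <id>.ann file pairs
#'
#' @param dir directory holding (or receiving) UTF-8 `<id>.txt` / `<id>.ann`
#'   pairs.
#' @return `readCorpus` returns a list of [Document-class]; `writeCorpus`
#'   invisibly returns the written document ids.
#' @export
readCorpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(f) {
    id <- sub("\\.txt$", "", basename(f))
    annFile <- file.path(dir, paste0(id, ".ann"))
    text <- readChar(f, file.size(f), useBytes = TRUE)
    Encoding(text) <- "UTF-8"
    ann <- if (file.exists(annFile)) {
      a <- readChar(annFile, file.size(annFile), useBytes = TRUE)
      Encoding(a) <- "UTF-8"
      a
    } else ""
    readDocument(text, ann, docId = id)
  })
}

#' @param docs list of [Document-class].
#' @rdname readCorpus
#' @export
writeCorpus <- function(docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in docs) {
    writeLines(docText(doc), file.path(dir, paste0(docId(doc), ".txt")),
               sep = "", useBytes = FALSE)
    cat(writeAnnotations(doc), file = file.path(dir, paste0(docId(doc), ".ann")))
  }
  invisible(vapply(docs, docId, character(1L)))
}
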