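#' @import methods
NULL

# --- internal span helpers -------------------------------------------------
# All offsets are 0-based, half-open, counted in Unicode code points.

substrCP <- function(text, start, end) substring(text, start + 1L, end)

emptyEntities <- function() {
  data.frame(id = character(), label = character(), start = integer(),
             end = integer(), surface = character(), stringsAsFactors = FALSE)
}

emptyRelations <- function() {
  data.frame(id = character(), label = character(), trigger = character(),
             argument = character(), stringsAsFactors = FALSE)
}

emptySpans <- function() {
  data.frame(start = integer(), end = integer(), stringsAsFactors = FALSE)
}

emptyTokens <- function() {
  data.frame(surface = character(), start = integer(), end = integer(),
             sentence = integer(), stringsAsFactors = FALSE)
}

emptyTraces <- function() {
  data.frame(rule = character(), docId = character(), before = character(),
             after = character(), stringsAsFactors = FALSE)
}

#' Document: an annotated patent snippet
#'
#' The central container of the package. A `Document` holds the raw snippet
#' text together with sentence spans, tokens, typed entity mentions and
#' trigger-argument relation mentions. All character offsets are 0-based and
#' half-open, counted in Unicode code points, following standoff-corpus
#' convention.
#'
#' @slot docId document identifier.
#' @slot text the raw snippet text.
#' @slot sentences data.frame with `start`, `end` spans, sorted and
#'   non-overlapping.
#' @slot tokens data.frame with `surface`, `start`, `end`, `sentence` (index
#'   into the sentence table) and optionally a `subwords` list column.
#' @slot entities data.frame with `id`, `label`, `start`, `end`, `surface`.
#' @slot relations data.frame with `id`, `label` (`ARG1`/`ARGM`), `trigger`
#'   and `argument` (entity ids; the trigger end is always an event trigger).
#' @slot ruleTraces data.frame audit log of postprocessing rule applications.
#'
#' @exportClass Document
setClass("Document",
  representation(docId = "character", text = "character",
                 sentences = "data.frame", tokens = "data.frame",
                 entities = "data.frame", relations = "data.frame",
                 ruleTraces = "data.frame"),
  prototype(docId = "doc", text = "", sentences = emptySpans(),
            tokens = emptyTokens(), entities = emptyEntities(),
            relations = emptyRelations(), ruleTraces = emptyTraces()))

validDocument <- function(object) {
  msgs <- character()
  n <- nchar(object@text)
  sen <- object@sentences
  if (nrow(sen)) {
    if (any(sen$start < 0L) || any(sen$end > n) || any(sen$start >= sen$end))
      msgs <- c(msgs, "sentence spans must satisfy 0 <= start < end <= nchar(text)")
    if (nrow(sen) > 1L && (is.unsorted(sen$start) ||
                           any(sen$start[-1L] < sen$end[-nrow(sen)])))
      msgs <- c(msgs, "sentence spans must be sorted and non-overlapping")
  }
  ent <- object@entities
  if (nrow(ent)) {
    if (anyDuplicated(ent$id))
      msgs <- c(msgs, "entity ids must be unique")
    if (!all(ent$label %in% entityLabels()))
      msgs <- c(msgs, paste0("unknown entity label(s): ",
                paste(setdiff(ent$label, entityLabels()), collapse = ", ")))
    if (any(ent$start < 0L) || any(ent$end > n) || any(ent$start >= ent$end))
      msgs <- c(msgs, "entity spans must satisfy 0 <= start < end <= nchar(text)")
    else {
      got <- substrCP(object@text, ent$start, ent$end)
      bad <- which(got != ent$surface)
      if (length(bad))
        msgs <- c(msgs, paste0("entity surface mismatch for ", ent$id[bad[1L]],
                  ": annotation says ", dQuote(ent$surface[bad[1L]]),
                  " but text reads ", dQuote(got[bad[1L]])))
    }
  }
  rel <- object@relations
  if (nrow(rel)) {
    if (anyDuplicated(rel$id))
      msgs <- c(msgs, "relation ids must be unique")
    if (!all(rel$label %in% c("ARG1", "ARGM")))
      msgs <- c(msgs, "relation labels must be ARG1 or ARGM")
    miss <- setdiff(c(rel$trigger, rel$argument), ent$id)
    if (length(miss))
      msgs <- c(msgs, paste0("relation endpoint(s) not among entities: ",
                             paste(miss, collapse = ", ")))
    else {
      tl <- ent$label[match(rel$trigger, ent$id)]
      al <- ent$label[match(rel$argument, ent$id)]
      if (!all(isTrigger(tl)))
        msgs <- c(msgs, "relation trigger endpoints must carry a trigger label")
      if (any(isTrigger(al)) || any(al == "EXAMPLE_LABEL"))
        msgs <- c(msgs, "relation arguments must be semantic roles other than EXAMPLE_LABEL")
      bad1 <- rel$label == "ARG1" & !al %in% arg1Roles()
      badm <- rel$label == "ARGM" & !al %in% argmRoles()
      if (any(bad1, na.rm = TRUE) || any(badm, na.rm = TRUE))
        msgs <- c(msgs, "ARG1 arguments must be compound roles and ARGM arguments auxiliary roles")
    }
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("Document", validDocument)

#' Construct a Document
#'
#' @param docId document identifier.
#' @param text raw snippet text.
#' @param sentences,tokens,entities,relations see the class slots.
#' @return a validated [Document-class] object.
#' @export
Document <- function(docId = "doc", text = "", sentences = emptySpans(),
                     tokens = emptyTokens(), entities = emptyEntities(),
                     relations = emptyRelations()) {
  new("Document", docId = docId, text = text, sentences = sentences,
      tokens = tokens, entities = entities, relations = relations,
      ruleTraces = emptyTraces())
}

#' @describeIn Document-class document identifier accessor
#' @param x,object a `Document`.
#' @export
docId <- function(x) x@docId

#' @describeIn Document-class raw text accessor
#' @export
docText <- function(x) x@text

#' @describeIn Document-class sentence span table accessor
#' @export
sentences <- function(x) x@sentences

#' @describeIn Document-class token table accessor
#' @export
tokens <- function(x) x@tokens

#' @describeIn Document-class entity mention table accessor
#' @export
entities <- function(x) x@entities

#' @describeIn Document-class relation mention table accessor
#' @export
relations <- function(x) x@relations

#' @describeIn Document-class postprocessing audit-trace accessor
#' @export
ruleTraces <- function(x) x@ruleTraces

#' @describeIn Document-class replace the entity table (relations referring to
#'   dropped entities are removed)
#' @param value replacement table.
#' @export
`entities<-` <- function(x, value) {
  x@entities <- value
  keep <- x@relations$trigger %in% value$id & x@relations$argument %in% value$id
  x@relations <- x@relations[keep, , drop = FALSE]
  rownames(x@relations) <- NULL
  validObject(x)
  x
}

#' @describeIn Document-class replace the relation table
#' @export
`relations<-` <- function(x, value) {
  x@relations <- value
  validObject(x)
  x
}

setMethod("show", "Document", function(object) {
  cat(sprintf("Document %s: %d chars, %d sentences, %d tokens, %d entities, %d relations\n",
              object@docId, nchar(object@text), nrow(object@sentences),
              nrow(object@tokens), nrow(object@entities), nrow(object@relations)))
  if (nrow(object@entities)) {
    tab <- table(object@entities$label)
    cat("  entities:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})
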