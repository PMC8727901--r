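# Deterministic postprocessing. NER repairs: trim lead words/brackets from
# example-heading identifiers, trim "compound"/"example" prefixes from
# numeric chemical identifiers, and relabel compounds in heading regions.
# Relation recovery: re-join clauses split at "sat. aq." and link yield
# sentences ("Yield: 15 mg (25% of theory).") back to the trigger of the
# previous sentence. Every change is recorded in the document's rule trace.

traceRecord <- function(rule, docId, before, after) {
  data.frame(rule = rule, docId = docId, before = before, after = after,
             stringsAsFactors = FALSE)
}

addTrace <- function(doc, rule, before, after) {
  doc@ruleTraces <- rbind(doc@ruleTraces,
                          traceRecord(rule, docId(doc), before, after))
  doc
}

describeEntity <- function(e) {
  sprintf("%s %s [%d,%d) %s", e$id, e$label, e$start, e$end, dQuote(e$surface))
}

exampleLeadWords <- function() {
  c("reference example", "example", "step", "intermediate", "core")
}

#' Trim lead words and brackets from an example-heading identifier
#'
#' Removes (case-insensitively) the words "example", "step", "intermediate",
#' "core" and "reference example", plus round/square/curly brackets, from the
#' edges of an `EXAMPLE_LABEL` mention by shrinking its offsets. The span is
#' only ever shrunk, never grown or moved; if trimming would empty the span
#' the mention is returned unchanged.
#'
#' @param entity one-row entity data.frame with label `EXAMPLE_LABEL`.
#' @param text the document text.
#' @return the (possibly shrunk) entity row, with attribute `changed`.
#' @examples
#' # "Example 95" -> "95"
#' @export
trimExampleLabel <- function(entity, text) {
  stopifnot(entity$label == "EXAMPLE_LABEL")
  s <- entity$start; e <- entity$end
  brackets <- c("(", ")", "[", "]", "{", "}")
  wouldEmpty <- FALSE
  repeat {
    moved <- FALSE
    while (s < e && (substrCP(text, s, s + 1L) %in% c(brackets, " ", "\t"))) {
      s <- s + 1L; moved <- TRUE
    }
    while (s < e && (substrCP(text, e - 1L, e) %in% c(brackets, " ", "\t"))) {
      e <- e - 1L; moved <- TRUE
    }
    rem <- tolower(substrCP(text, s, e))
    for (w in exampleLeadWords()) {
      if (startsWith(rem, w) &&
          (nchar(rem) == nchar(w) ||
           grepl("^[^[:alnum:]]", substr(rem, nchar(w) + 1L, nchar(w) + 1L)))) {
        s2 <- s + nchar(w)
        if (s2 < e) { s <- s2; moved <- TRUE } else wouldEmpty <- TRUE
        break
      }
    }
    if (!moved) break
  }
  if (s >= e || wouldEmpty) {  # trimming would empty the span; leave untouched
    attr(entity, "changed") <- FALSE
    attr(entity, "warning") <- TRUE
    return(entity)
  }
  changed <- s != entity$start || e != entity$end
  entity$start <- s; entity$end <- e
  entity$surface <- substrCP(text, s, e)
  attr(entity, "changed") <- changed
  entity
}

#' Trim "compound"/"example"/"immediate" prefixes from numeric chemical ids
#'
#' When a compound-type mention starts with one of the lead words and the
#' remainder is a numeric or mixed number-letter identifier (e.g. "compound
#' 1-0003", "Example 56A"), the lead word is removed by shrinking the start
#' offset. Mentions whose remainder is not numeric are left untouched.
#'
#' @param entity one-row entity data.frame with a compound-type role label.
#' @param text the document text.
#' @return the (possibly shrunk) entity row, with attribute `changed`.
#' @export
trimCompoundPrefix <- function(entity, text) {
  stopifnot(entity$label %in% arg1Roles())
  surf <- entity$surface
  for (w in c("compound", "example", "immediate")) {
    m <- regexpr(paste0("^", w, "\\s+"), surf, ignore.case = TRUE)
    if (m == 1L) {
      rest <- substr(surf, attr(m, "match.length") + 1L, nchar(surf))
      if (grepl("^[0-9][0-9A-Za-z-]*$", rest)) {
        entity$start <- entity$start + attr(m, "match.length")
        entity$surface <- rest
        attr(entity, "changed") <- TRUE
        return(entity)
      }
    }
  }
  attr(entity, "changed") <- FALSE
  entity
}

sentenceText <- function(doc, i) {
  substrCP(docText(doc), sentences(doc)$start[i], sentences(doc)$end[i])
}

entitySentence <- function(doc, startOffset) {
  sen <- sentences(doc)
  idx <- which(sen$start <= startOffset & startOffset < sen$end)
  if (length(idx)) idx[1L] else NA_integer_
}

#' Relabel compound mentions in heading regions
#'
#' Patent snippets often open with a top-level example heading naming the
#' compounds of the whole example, followed by a sub-step heading (an
#' identifier like "48.1") naming the actual target of the described
#' reaction. When a sub-step heading is present, compound mentions in the
#' top-level heading region describe the overall example, not this reaction,
#' so they are relabeled `OTHER_COMPOUND`; the compound named by the sub-step
#' heading region is the product of the described step and receives
#' `REACTION_PRODUCT`.
#'
#' @param doc a segmented [Document-class] with entities.
#' @return the document, possibly with relabeled mentions and trace records.
#' @export
relabelHeadingCompounds <- function(doc) {
  sen <- sentences(doc)
  if (nrow(sen) < 2L || !nrow(entities(doc))) return(doc)
  txt <- vapply(seq_len(nrow(sen)), function(i) trimws(sentenceText(doc, i)),
                character(1L))
  topIdx <- which(grepl("^(EXAMPLE|Example)\\s+\\S+", txt) &
                  !grepl("^\\S+\\s+\\d+\\.\\d+", txt))[1L]
  subIdx <- which(grepl("^\\d+\\.\\d+$", txt) |
                  grepl("^(EXAMPLE|Example|Step)\\s+\\d+\\.\\d+$", txt))[1L]
  if (is.na(topIdx) || is.na(subIdx) || subIdx <= topIdx) return(doc)
  ent <- entities(doc)
  compound <- ent$label %in% c("REACTION_PRODUCT", "OTHER_COMPOUND")
  si <- vapply(ent$start, function(s) entitySentence(doc, s), integer(1L))
  bodyStart <- min(subIdx + 2L, nrow(sen) + 1L)
  for (k in which(compound)) {
    region <- if (!is.na(si[k]) && si[k] >= topIdx && si[k] < subIdx) "top"
      else if (!is.na(si[k]) && si[k] >= subIdx && si[k] < bodyStart) "sub"
      else next
    want <- if (region == "top") "OTHER_COMPOUND" else "REACTION_PRODUCT"
    if (ent$label[k] != want) {
      before <- describeEntity(ent[k, ])
      ent$label[k] <- want
      doc <- addTrace(doc, "relabel_heading_compounds", before,
                      describeEntity(ent[k, ]))
    }
  }
  doc@entities <- ent
  validObject(doc)
  doc
}

#' Apply the NER span/label repair rules to a document
#'
#' Runs [relabelHeadingCompounds()], [trimExampleLabel()] and
#' [trimCompoundPrefix()] over all applicable mentions, tracing each change.
#'
#' @param doc a segmented [Document-class] with (predicted) entities.
#' @return the repaired document.
#' @export
applyNerRules <- function(doc) {
  doc <- relabelHeadingCompounds(doc)
  ent <- entities(doc)
  for (k in seq_len(nrow(ent))) {
    row <- ent[k, ]
    fixed <- if (row$label == "EXAMPLE_LABEL")
      trimExampleLabel(row, docText(doc))
    else if (row$label %in% arg1Roles())
      trimCompoundPrefix(row, docText(doc))
    else next
    if (isTRUE(attr(fixed, "warning")))
      doc <- addTrace(doc, "trim_example_label", describeEntity(row),
                      "unchanged (trim would empty span)")
    if (isTRUE(attr(fixed, "changed"))) {
      rule <- if (row$label == "EXAMPLE_LABEL") "trim_example_label"
        else "trim_compound_prefix"
      doc <- addTrace(doc, rule, describeEntity(row), describeEntity(fixed))
      ent[k, c("start", "end", "surface")] <-
        fixed[, c("start", "end", "surface")]
    }
  }
  doc@entities <- ent
  validObject(doc)
  doc
}

nextRelationId <- function(doc) {
  ids <- relations(doc)$id
  nums <- suppressWarnings(as.integer(sub("^R", "", ids)))
  paste0("R", if (length(nums) && any(!is.na(nums))) max(nums, na.rm = TRUE) + 1L else 1L)
}

hasRelation <- function(doc, trigger, argument) {
  rel <- relations(doc)
  any(rel$trigger == trigger & rel$argument == argument)
}

addRelation <- function(doc, trigger, argument, rule) {
  ent <- entities(doc)
  lab <- assignRelationLabel(ent$label[match(trigger, ent$id)],
                             ent$label[match(argument, ent$id)])
  rel <- data.frame(id = nextRelationId(doc), label = lab, trigger = trigger,
                    argument = argument, stringsAsFactors = FALSE)
  doc@relations <- rbind(relations(doc), rel)
  validObject(doc)
  addTrace(doc, rule, "created",
           sprintf("%s %s Arg1:%s Arg2:%s", rel$id, lab, trigger, argument))
}

#' Re-join "sat. aq." splits and link the chemical that follows
#'
#' A sentence splitter unaware of the "sat. aq." (saturated aqueous)
#' abbreviation severs clauses like "washed with sat. aq. | NH4Cl". This rule
#' merges such a split (sentence ending in "sat. aq." followed by a sentence
#' opening with a compound mention) and then, for every "sat. aq."
#' occurrence, creates the missing relation between an event trigger of the
#' clause and the chemical that follows the abbreviation.
#'
#' @param doc a segmented [Document-class] with entities (and possibly
#'   relations).
#' @param strategy trigger choice: `"nearest"` takes the closest preceding
#'   trigger in the clause; `"clause-head"` takes the clause's first trigger.
#' @return the document with merged sentences and recovered relations.
#' @export
mergeSatAqAndLink <- function(doc, strategy = c("nearest", "clause-head")) {
  strategy <- match.arg(strategy)
  compoundLabels <- arg1Roles()
  # merge pass
  repeat {
    sen <- sentences(doc)
    merged <- FALSE
    for (i in seq_len(max(0L, nrow(sen) - 1L))) {
      if (!grepl("sat\\. aq\\.$", trimws(sentenceText(doc, i)))) next
      nxt <- sen$start[i + 1L]
      ent <- entities(doc)
      opensWithChem <- any(ent$label %in% compoundLabels & ent$start == nxt)
      if (!opensWithChem) next
      before <- sprintf("sentences [%d,%d) + [%d,%d)", sen$start[i], sen$end[i],
                        sen$start[i + 1L], sen$end[i + 1L])
      sen$end[i] <- sen$end[i + 1L]
      sen <- sen[-(i + 1L), , drop = FALSE]
      rownames(sen) <- NULL
      doc@sentences <- sen
      toks <- tokens(doc)
      if (nrow(toks)) {
        toks$sentence[toks$sentence == i + 1L] <- i
        toks$sentence[toks$sentence > i + 1L] <- toks$sentence[toks$sentence > i + 1L] - 1L
        doc@tokens <- toks
      }
      doc <- addTrace(doc, "merge_sat_aq", before,
                      sprintf("merged to [%d,%d)", sen$start[i], sen$end[i]))
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  # linking pass: every "sat. aq." occurrence
  occ <- gregexpr("sat. aq.", docText(doc), fixed = TRUE)[[1L]]
  if (occ[1L] == -1L) return(doc)
  ent <- entities(doc)
  for (p in as.integer(occ)) {
    endPos <- p - 1L + 8L  # 0-based end of the occurrence
    si <- entitySentence(doc, endPos - 1L)
    if (is.na(si)) next
    senEnd <- sentences(doc)$end[si]
    chems <- which(ent$label %in% compoundLabels & ent$start >= endPos &
                   ent$end <= senEnd)
    if (!length(chems)) next
    chem <- chems[which.min(ent$start[chems])]
    trigs <- which(isTrigger(ent$label) & ent$end <= ent$start[chem] &
                   ent$start >= sentences(doc)$start[si])
    if (!length(trigs)) next
    trig <- if (strategy == "nearest") trigs[which.max(ent$start[trigs])]
      else trigs[which.min(ent$start[trigs])]
    if (!hasRelation(doc, ent$id[trig], ent$id[chem]))
      doc <- addRelation(doc, ent$id[trig], ent$id[chem], "merge_sat_aq_link")
  }
  doc
}

#' Link standalone yield sentences to the previous sentence's trigger
#'
#' Yields are often reported in their own sentence ("Yield: 15 mg (25% of
#' theory)."), out of reach of the within-sentence relation classifier. For
#' each sentence starting with "Yield" + colon that contains yield mentions,
#' ARGM relations are created from the last event trigger of the previous
#' sentence to each yield mention. If the previous sentence has no trigger
#' (or the yield sentence opens the document), a warning trace is emitted
#' and nothing is linked.
#'
#' @param doc a segmented [Document-class] with entities.
#' @return the document with recovered ARGM relations.
#' @export
linkYieldSentence <- function(doc) {
  sen <- sentences(doc)
  ent <- entities(doc)
  if (nrow(sen) < 1L || !nrow(ent)) return(doc)
  for (i in seq_len(nrow(sen))) {
    if (!grepl("^Yield\\s*:", trimws(sentenceText(doc, i)))) next
    yields <- which(ent$label %in% c("YIELD_OTHER", "YIELD_PERCENT") &
                    ent$start >= sen$start[i] & ent$end <= sen$end[i])
    if (!length(yields)) next
    if (i == 1L) {
      doc <- addTrace(doc, "link_yield_sentence",
                      sprintf("yield sentence %d", i),
                      "skipped (no previous sentence)")
      next
    }
    trigs <- which(isTrigger(ent$label) & ent$start >= sen$start[i - 1L] &
                   ent$end <= sen$end[i - 1L])
    if (!length(trigs)) {
      doc <- addTrace(doc, "link_yield_sentence",
                      sprintf("yield sentence %d", i),
                      "skipped (previous sentence has no trigger)")
      next
    }
    trig <- trigs[which.max(ent$start[trigs])]
    for (y in yields) {
      if (!hasRelation(doc, ent$id[trig], ent$id[y]))
        doc <- addRelation(doc, ent$id[trig], ent$id[y], "link_yield_sentence")
    }
  }
  doc
}

#' Apply the relation recovery rules
#'
#' @param doc a segmented [Document-class] with entities and relations.
#' @param satAqStrategy trigger-choice strategy for [mergeSatAqAndLink()].
#' @return the document after [mergeSatAqAndLink()] and
#'   [linkYieldSentence()].
#' @export
applyRelationRules <- function(doc, satAqStrategy = "nearest") {
  doc <- mergeSatAqAndLink(doc, strategy = satAqStrategy)
  linkYieldSentence(doc)
}

#' Write rule traces as tab-separated log lines
#'
#' @param doc a [Document-class].
#' @param con connection or file path ("" prints to stdout).
#' @export
writeRuleTraces <- function(doc, con = "") {
  tr <- ruleTraces(doc)
  if (!nrow(tr)) return(invisible(character()))
  lines <- sprintf("%s\t%s\t%s\t%s", tr$rule, tr$docId, tr$before, tr$after)
  writeLines(lines, con)
  invisible(lines)
}
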