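# Exact and relaxed matching of entity and relation mentions with per-type
# and overall precision/recall/F1. Exact matching requires identical label
# and identical character span; relaxed matching requires identical label
# and any character overlap. Matching is one-to-one, resolved greedily by
# largest overlap then earliest start.

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

spanOverlap <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

# One-to-one greedy matching of two span sets (same label assumed).
# Returns indices: matched pred index per gold (NA if unmatched).
matchSpans <- function(gold, pred, mode) {
  if (!nrow(gold) || !nrow(pred))
    return(rep(NA_integer_, nrow(gold)))
  pairs <- expand.grid(g = seq_len(nrow(gold)), p = seq_len(nrow(pred)))
  ov <- spanOverlap(gold$start[pairs$g], gold$end[pairs$g],
                    pred$start[pairs$p], pred$end[pairs$p])
  ok <- if (mode == "exact")
    gold$start[pairs$g] == pred$start[pairs$p] &
    gold$end[pairs$g] == pred$end[pairs$p]
  else ov > 0L
  pairs <- pairs[ok, , drop = FALSE]; ov <- ov[ok]
  ord <- order(-ov, gold$start[pairs$g], pred$start[pairs$p])
  pairs <- pairs[ord, , drop = FALSE]
  out <- rep(NA_integer_, nrow(gold))
  usedP <- logical(nrow(pred))
  for (k in seq_len(nrow(pairs))) {
    g <- pairs$g[k]; p <- pairs$p[k]
    if (is.na(out[g]) && !usedP[p]) { out[g] <- p; usedP[p] <- TRUE }
  }
  out
}

#' Match entity mention sets and count tp/fp/fn per label
#'
#' @param gold,pred entity data.frames from the same document text.
#' @param mode `"exact"` (same label, same span) or `"relaxed"` (same label,
#'   overlapping span).
#' @return data.frame with columns `label`, `tp`, `fp`, `fn`.
#' @export
matchEntities <- function(gold, pred, mode = c("exact", "relaxed")) {
  mode <- match.arg(mode)
  labs <- sort(unique(c(gold$label, pred$label)))
  rows <- lapply(labs, function(lab) {
    g <- gold[gold$label == lab, , drop = FALSE]
    p <- pred[pred$label == lab, , drop = FALSE]
    m <- matchSpans(g, p, mode)
    tp <- sum(!is.na(m))
    data.frame(label = lab, tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(label = character(), tp = integer(), fp = integer(),
                      fn = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

relationTriples <- function(rel, ent) {
  if (!nrow(rel))
    return(data.frame(label = character(), tStart = integer(), tEnd = integer(),
                      tLabel = character(), aStart = integer(), aEnd = integer(),
                      aLabel = character(), triple = character(),
                      stringsAsFactors = FALSE))
  ti <- match(rel$trigger, ent$id); ai <- match(rel$argument, ent$id)
  data.frame(label = rel$label,
             tStart = ent$start[ti], tEnd = ent$end[ti], tLabel = ent$label[ti],
             aStart = ent$start[ai], aEnd = ent$end[ai], aLabel = ent$label[ai],
             triple = paste(rel$label, ent$label[ti], ent$label[ai], sep = "|"),
             stringsAsFactors = FALSE)
}

#' Match relation mention sets and count tp/fp/fn per relation type
#'
#' A predicted relation matches a gold relation iff the relation labels are
#' equal and both endpoint mentions match under the chosen entity mode
#' (exact span or overlap, with equal entity label). Counts are grouped by
#' the `LABEL|TRIGGER_TYPE|ARGUMENT_TYPE` triple.
#'
#' @param gold,pred relation data.frames.
#' @param goldEnt,predEnt the entity tables resolving their endpoints.
#' @param mode `"exact"` or `"relaxed"`.
#' @return data.frame with columns `label` (the triple), `tp`, `fp`, `fn`.
#' @export
matchRelations <- function(gold, pred, goldEnt, predEnt,
                           mode = c("exact", "relaxed")) {
  mode <- match.arg(mode)
  g <- relationTriples(gold, goldEnt)
  p <- relationTriples(pred, predEnt)
  endpointOk <- function(gs, ge, ps, pe) {
    if (mode == "exact") gs == ps & ge == pe else spanOverlap(gs, ge, ps, pe) > 0L
  }
  matchedP <- logical(nrow(p))
  matchedG <- logical(nrow(g))
  if (nrow(g) && nrow(p)) {
    pairs <- expand.grid(g = seq_len(nrow(g)), p = seq_len(nrow(p)))
    ok <- g$triple[pairs$g] == p$triple[pairs$p] &
      endpointOk(g$tStart[pairs$g], g$tEnd[pairs$g],
                 p$tStart[pairs$p], p$tEnd[pairs$p]) &
      endpointOk(g$aStart[pairs$g], g$aEnd[pairs$g],
                 p$aStart[pairs$p], p$aEnd[pairs$p])
    pairs <- pairs[ok, , drop = FALSE]
    ov <- spanOverlap(g$tStart[pairs$g], g$tEnd[pairs$g],
                      p$tStart[pairs$p], p$tEnd[pairs$p]) +
          spanOverlap(g$aStart[pairs$g], g$aEnd[pairs$g],
                      p$aStart[pairs$p], p$aEnd[pairs$p])
    ord <- order(-ov, g$tStart[pairs$g], g$aStart[pairs$g])
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      gi <- pairs$g[k]; pi <- pairs$p[k]
      if (!matchedG[gi] && !matchedP[pi]) {
        matchedG[gi] <- TRUE; matchedP[pi] <- TRUE
      }
    }
  }
  labs <- sort(unique(c(g$triple, p$triple)))
  rows <- lapply(labs, function(lab) {
    data.frame(label = lab,
               tp = sum(matchedG & g$triple == lab),
               fp = sum(!matchedP & p$triple == lab),
               fn = sum(!matchedG & g$triple == lab),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(label = character(), tp = integer(), fp = integer(),
                      fn = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' EvalReport: per-type and overall precision/recall/F1
#'
#' @slot perLabel data.frame: `label`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @slot overall one-row data.frame with the same metric columns (counts are
#'   the sums of the per-label counts).
#' @slot mode `"exact"` or `"relaxed"`.
#' @slot task `"ner"`, `"relation"` or `"end_to_end"`.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(perLabel = "data.frame", overall = "data.frame",
                 mode = "character", task = "character"))

setValidity("EvalReport", function(object) {
  pl <- object@perLabel; ov <- object@overall
  if (nrow(pl) &&
      (sum(pl$tp) != ov$tp || sum(pl$fp) != ov$fp || sum(pl$fn) != ov$fn))
    return("overall counts must equal the sums of per-label counts")
  TRUE
})

withMetrics <- function(counts) {
  m <- t(vapply(seq_len(nrow(counts)),
                function(i) prf(counts$tp[i], counts$fp[i], counts$fn[i]),
                numeric(3L)))
  cbind(counts, as.data.frame(m))
}

buildReport <- function(counts, mode, task) {
  perLabel <- withMetrics(counts)
  overall <- withMetrics(data.frame(label = "Overall", tp = sum(counts$tp),
                                    fp = sum(counts$fp), fn = sum(counts$fn),
                                    stringsAsFactors = FALSE))
  new("EvalReport", perLabel = perLabel, overall = overall,
      mode = mode, task = task)
}

#' Score predicted documents against gold documents
#'
#' Aggregates tp/fp/fn counts over all documents (aligned by id), then
#' computes precision, recall and F1 per type and overall. The zero
#' denominator convention is 0 for all three metrics. For the `end_to_end`
#' task the predicted documents are expected to carry pipeline-predicted
#' entities (so entity errors propagate into relation scores); the scoring
#' mechanics are those of the `relation` task.
#'
#' @param goldDocs,predDocs lists of [Document-class], ids aligned
#'   one-to-one.
#' @param task `"ner"`, `"relation"` or `"end_to_end"`.
#' @param mode `"exact"` or `"relaxed"`.
#' @return an [EvalReport-class].
#' @examples
#' # tp=2, fp=1, fn=1 gives P = R = F1 = 2/3 by direct substitution
#' @export
score <- function(goldDocs, predDocs, task = c("ner", "relation", "end_to_end"),
                  mode = c("exact", "relaxed")) {
  task <- match.arg(task); mode <- match.arg(mode)
  gid <- vapply(goldDocs, docId, character(1L))
  pid <- vapply(predDocs, docId, character(1L))
  if (length(gid) != length(pid) || !setequal(gid, pid) || anyDuplicated(gid))
    stop("gold and predicted document ids must align one-to-one")
  predDocs <- predDocs[match(gid, pid)]
  counts <- list()
  for (i in seq_along(goldDocs)) {
    g <- goldDocs[[i]]; p <- predDocs[[i]]
    counts[[i]] <- if (task == "ner")
      matchEntities(entities(g), entities(p), mode)
    else
      matchRelations(relations(g), relations(p), entities(g), entities(p), mode)
  }
  all <- do.call(rbind, counts)
  agg <- if (!is.null(all) && nrow(all)) {
    a <- stats::aggregate(cbind(tp, fp, fn) ~ label, data = all, FUN = sum)
    a[order(a$label), , drop = FALSE]
  } else data.frame(label = character(), tp = integer(), fp = integer(),
                    fn = integer(), stringsAsFactors = FALSE)
  buildReport(agg, mode, task)
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: task %s, %s matching\n", object@task, object@mode))
  tab <- rbind(object@perLabel, object@overall)
  tab$precision <- sprintf("%.4f", tab$precision)
  tab$recall <- sprintf("%.4f", tab$recall)
  tab$f1 <- sprintf("%.4f", tab$f1)
  print(tab, row.names = FALSE)
})

#' Serialize an evaluation report to JSON
#'
#' Rows keyed by type name plus an `"Overall"` row, each carrying counts and
#' metrics, plus `mode` and `task` fields.
#'
#' @param report an [EvalReport-class].
#' @param path optional output file.
#' @return the JSON string, invisibly if written to `path`.
#' @export
reportJSON <- function(report, path = NULL) {
  rows <- rbind(report@perLabel, report@overall)
  payload <- list(task = report@task, mode = report@mode,
                  results = stats::setNames(lapply(seq_len(nrow(rows)), function(i)
                    as.list(rows[i, c("tp", "fp", "fn", "precision", "recall", "f1")])),
                    rows$label))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}
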