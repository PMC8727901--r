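# Templated generator of annotated reaction snippets. Documents mimic the
# phenomena of patent reaction text that the pipeline has to handle:
# example headings with identifiers, optional sub-step headings naming the
# step's target compound, reaction sentences with punctuation-rich
# IUPAC-like names, workup sentences, "sat. aq." clauses and standalone
# "Yield:" sentences. Gold entities and relations follow the ARG1/ARGM
# schema, so every stage of the cascade can train and evaluate offline.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generator configuration
#'
#' The fractions control how often the phenomena targeted by the
#' postprocessing rules appear: sub-step headings (compound relabeling),
#' "sat. aq." clauses (clause merge and trigger linking) and standalone
#' "Yield:" sentences (cross-sentence ARGM recovery).
#'
#' @param nDocuments number of documents to generate.
#' @param seed integer seed; the same configuration always yields a
#'   byte-identical corpus.
#' @param substepFraction,satAqFraction,yieldSentenceFraction probabilities
#'   in `[0, 1]`.
#' @return a named list.
#' @export
generatorConfig <- function(nDocuments = 100L, seed = 1L,
                            substepFraction = 0.3, satAqFraction = 0.2,
                            yieldSentenceFraction = 0.3) {
  probs <- c(substepFraction, satAqFraction, yieldSentenceFraction)
  if (any(probs < 0) || any(probs > 1))
    stop("fractions must lie in [0, 1]")
  if (nDocuments < 0) stop("nDocuments must be >= 0")
  list(nDocuments = as.integer(nDocuments), seed = as.integer(seed),
       substepFraction = substepFraction, satAqFraction = satAqFraction,
       yieldSentenceFraction = yieldSentenceFraction)
}

# --- lexicons --------------------------------------------------------------

genLexicon <- function() {
  list(
    substituents = c("bromo", "chloro", "fluoro", "methyl", "ethyl",
                     "methoxy", "nitro", "amino", "hydroxy", "cyano"),
    heterocycles = c("pyridin", "pyrimidin", "pyrazol", "thiophen", "furan",
                     "oxazol", "imidazol"),
    cores = c("oxazine", "quinoline", "indole", "benzamide", "piperidine",
              "morpholine", "acetamide", "benzoate", "chromen-2-one",
              "naphthyridine"),
    solvents = c("DMF", "THF", "EtOAc", "dichloromethane", "methanol",
                 "toluene", "acetonitrile", "DMSO", "ethanol", "dioxane"),
    reagents = c("NaH", "K2CO3", "Pd(PPh3)4", "Et3N", "NaBH4", "TFA",
                 "NaOH", "AcOH", "DIPEA", "HATU"),
    others = c("NH4Cl", "NaCl", "Na2SO4", "MgSO4", "NaHCO3", "Na2CO3",
               "LiCl", "KHSO4"),
    stepVerbs = c("stirred", "heated", "treated", "dissolved", "cooled",
                  "refluxed", "added"),
    workupVerbs = c("washed", "dried", "filtered", "concentrated",
                    "extracted"),
    temperatures = c("0 ° C", "25 ° C", "50 ° C", "80 ° C",
                     "100 ° C", "110 ° C"),
    times = c("2 h", "16 h", "30 min", "1 h", "12 h", "4 h"))
}

# Compositional IUPAC-like names: locants, hyphens, brackets and suffixes
# that exercise the punctuation-separator tokenizer.
makeChemName <- function(lex) {
  d <- function(hi) sample.int(hi, 1L)
  form <- sample.int(3L, 1L)
  if (form == 1L) {
    sprintf("%d-%s-%d-(%s-%d-yl)-%s", d(9L), sample(lex$substituents, 1L),
            d(9L), sample(lex$heterocycles, 1L), d(4L), sample(lex$cores, 1L))
  } else if (form == 2L) {
    sprintf("%d,%d-di%s-2H-benzo(b)(1,%d)%s", d(4L), d(4L) + 4L,
            sample(lex$substituents, 1L), d(4L), sample(lex$cores, 1L))
  } else {
    sprintf("N-(%d-%s phenyl)-%d-%s-%s", d(4L), sample(lex$substituents, 1L),
            d(9L), sample(lex$substituents, 1L), sample(lex$cores, 1L))
  }
}

# --- document builder ------------------------------------------------------

newBuilder <- function(docId) {
  env <- new.env(parent = emptyenv())
  env$docId <- docId
  env$text <- ""
  env$ents <- list()
  env$rels <- list()
  env
}

bText <- function(b, s) { b$text <- paste0(b$text, s); invisible(NULL) }

bEntity <- function(b, label, surface) {
  start <- nchar(b$text)
  bText(b, surface)
  id <- paste0("T", length(b$ents) + 1L)
  b$ents[[length(b$ents) + 1L]] <- data.frame(
    id = id, label = label, start = start, end = start + nchar(surface),
    surface = surface, stringsAsFactors = FALSE)
  id
}

bRelation <- function(b, trigger, argument) {
  ents <- do.call(rbind, b$ents)
  lab <- assignRelationLabel(ents$label[match(trigger, ents$id)],
                             ents$label[match(argument, ents$id)])
  b$rels[[length(b$rels) + 1L]] <- data.frame(
    id = paste0("R", length(b$rels) + 1L), label = lab, trigger = trigger,
    argument = argument, stringsAsFactors = FALSE)
  invisible(NULL)
}

bDocument <- function(b) {
  Document(docId = b$docId, text = b$text,
           entities = if (length(b$ents)) do.call(rbind, b$ents) else emptyEntities(),
           relations = if (length(b$rels)) do.call(rbind, b$rels) else emptyRelations())
}

generateDocument <- function(docId, cfg, lex) {
  b <- newBuilder(docId)
  exNum <- sample.int(400L, 1L)
  substep <- stats::runif(1L) < cfg$substepFraction
  satAq <- stats::runif(1L) < cfg$satAqFraction
  yieldSep <- stats::runif(1L) < cfg$yieldSentenceFraction

  bText(b, "EXAMPLE ")
  bEntity(b, "EXAMPLE_LABEL", as.character(exNum))
  bText(b, "\n")
  if (substep) {
    bEntity(b, "OTHER_COMPOUND", makeChemName(lex))
    bText(b, " and ")
    bEntity(b, "OTHER_COMPOUND", makeChemName(lex))
    bText(b, paste0("\n", exNum, ".1\n"))
    bEntity(b, "REACTION_PRODUCT", makeChemName(lex))
    bText(b, "\n")
  }

  # reaction sentence
  tmpl <- sample.int(2L, 1L)
  if (tmpl == 1L) {
    bText(b, "A solution of ")
    sm <- bEntity(b, "STARTING_MATERIAL", makeChemName(lex))
    bText(b, sprintf(" (%d.%d mg) in ", sample.int(90L, 1L), sample.int(9L, 1L)))
    sol <- bEntity(b, "SOLVENT", sample(lex$solvents, 1L))
    bText(b, " was ")
    trig <- bEntity(b, "REACTION_STEP",
                    sample(setdiff(lex$stepVerbs, "added"), 1L))
    bText(b, " at ")
    temp <- bEntity(b, "TEMPERATURE", sample(lex$temperatures, 1L))
    bText(b, " for ")
    tim <- bEntity(b, "TIME", sample(lex$times, 1L))
    bText(b, ". ")
    for (a in c(sm, sol, temp, tim)) bRelation(b, trig, a)
  } else {
    rg <- bEntity(b, "REAGENT_CATALYST", sample(lex$reagents, 1L))
    bText(b, sprintf(" (%d mg) was ", sample.int(500L, 1L)))
    trig <- bEntity(b, "REACTION_STEP", "added")
    bText(b, " to a mixture of ")
    sm <- bEntity(b, "STARTING_MATERIAL", makeChemName(lex))
    bText(b, " in ")
    sol <- bEntity(b, "SOLVENT", sample(lex$solvents, 1L))
    bText(b, " at ")
    temp <- bEntity(b, "TEMPERATURE", sample(lex$temperatures, 1L))
    bText(b, ". ")
    for (a in c(rg, sm, sol, temp)) bRelation(b, trig, a)
  }

  # workup sentence
  if (satAq) {
    bText(b, "The residue was ")
    t1 <- bEntity(b, "REACTION_STEP", "dissolved")
    bText(b, " in ")
    sol2 <- bEntity(b, "SOLVENT", sample(lex$solvents, 1L))
    bText(b, " and ")
    t2 <- bEntity(b, "WORKUP", "washed")
    bText(b, " with sat. aq. ")
    oc <- bEntity(b, "OTHER_COMPOUND", sample(lex$others, 1L))
    bText(b, ". ")
    bRelation(b, t1, sol2)
    bRelation(b, t2, oc)
  } else {
    bText(b, "The reaction mixture was ")
    t1 <- bEntity(b, "WORKUP", sample(c("washed", "extracted"), 1L))
    bText(b, " with ")
    oc1 <- bEntity(b, "OTHER_COMPOUND", sample(lex$others, 1L))
    bText(b, " and ")
    t2 <- bEntity(b, "WORKUP", "dried")
    bText(b, " over ")
    oc2 <- bEntity(b, "OTHER_COMPOUND", sample(lex$others, 1L))
    bText(b, ". ")
    bRelation(b, t1, oc1)
    bRelation(b, t2, oc2)
  }

  # product / yield sentence(s)
  if (yieldSep) {
    bText(b, "The mixture is ")
    tp <- bEntity(b, "WORKUP", "purified")
    bText(b, " by RP-HPLC to give ")
    prod <- bEntity(b, "REACTION_PRODUCT", makeChemName(lex))
    bText(b, ". Yield: ")
    yo <- bEntity(b, "YIELD_OTHER", sprintf("%d mg", sample.int(200L, 1L)))
    bText(b, " (")
    yp <- bEntity(b, "YIELD_PERCENT", sprintf("%d%%", sample.int(99L, 1L)))
    bText(b, " of theory).\n")
    bRelation(b, tp, prod)
    bRelation(b, tp, yo)   # cross-sentence, recovered by the yield rule
    bRelation(b, tp, yp)
  } else {
    bText(b, "The residue was ")
    tp <- bEntity(b, "WORKUP", "purified")
    bText(b, " by column chromatography to give ")
    prod <- bEntity(b, "REACTION_PRODUCT", makeChemName(lex))
    bText(b, " (")
    yo <- bEntity(b, "YIELD_OTHER", sprintf("%d mg", sample.int(200L, 1L)))
    bText(b, ", ")
    yp <- bEntity(b, "YIELD_PERCENT", sprintf("%d%%", sample.int(99L, 1L)))
    bText(b, ").\n")
    for (a in c(prod, yo, yp)) bRelation(b, tp, a)
  }
  tokenizeDocument(bDocument(b))
}

#' Generate a synthetic annotated corpus
#'
#' @param config see [generatorConfig()].
#' @return list of tokenized [Document-class] with gold entities and
#'   relations.
#' @examples
#' docs <- generateCorpus(generatorConfig(nDocuments = 3, seed = 7))
#' corpusStats(docs)$entities
#' @export
generateCorpus <- function(config = generatorConfig()) {
  if (is.null(config$nDocuments) || config$nDocuments < 0L)
    stop("invalid generator configuration")
  lex <- genLexicon()
  withSeed(config$seed, {
    lapply(seq_len(config$nDocuments), function(i)
      generateDocument(sprintf("synth%04d", i), config, lex))
  })
}

#' Corpus summary statistics
#'
#' @param docs list of [Document-class].
#' @return list with `documents`, `sentences`, `tokens` counts, an
#'   `entities` table (count per label, zeros included) and a `relations`
#'   table (count per `LABEL|TRIGGER|ARGUMENT` triple).
#' @export
corpusStats <- function(docs) {
  entLab <- unlist(lapply(docs, function(d) entities(d)$label))
  entCount <- table(factor(entLab, levels = entityLabels()))
  triples <- unlist(lapply(docs, function(d) {
    rel <- relations(d); ent <- entities(d)
    if (!nrow(rel)) return(character())
    paste(rel$label, ent$label[match(rel$trigger, ent$id)],
          ent$label[match(rel$argument, ent$id)], sep = "|")
  }))
  list(documents = length(docs),
       sentences = sum(vapply(docs, function(d) nrow(sentences(d)), integer(1L))),
       tokens = sum(vapply(docs, function(d) nrow(tokens(d)), integer(1L))),
       entities = data.frame(label = names(entCount),
                             count = as.integer(entCount),
                             stringsAsFactors = FALSE),
       relations = if (length(triples)) {
         tab <- sort(table(triples), decreasing = TRUE)
         data.frame(triple = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
       } else data.frame(triple = character(), count = integer(),
                         stringsAsFactors = FALSE))
}

#' Write a corpus as train/dev/test standoff directories
#'
#' Splits the documents 0.6/0.15/0.25 in order and writes `<id>.txt` /
#' `<id>.ann` pairs into `train/`, `dev/` and `test/` under `dir`.
#'
#' @param docs list of [Document-class].
#' @param dir output directory.
#' @param ratios named numeric vector summing to 1.
#' @return invisible list of the three id vectors.
#' @export
writeCorpusSplit <- function(docs, dir,
                             ratios = c(train = 0.6, dev = 0.15, test = 0.25)) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8)
  n <- length(docs)
  nTrain <- round(n * ratios[["train"]])
  nDev <- round(n * ratios[["dev"]])
  idx <- list(train = seq_len(nTrain),
              dev = seq_len(nDev) + nTrain,
              test = seq_len(n - nTrain - nDev) + nTrain + nDev)
  out <- lapply(names(idx), function(part) {
    writeCorpus(docs[idx[[part]]], file.path(dir, part))
  })
  invisible(stats::setNames(out, names(idx)))
}
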