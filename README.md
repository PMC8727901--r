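# ChemPatentIE

Reaction information extraction from chemical patent text in R: named-entity
recognition of reaction roles, relation extraction between reaction-step
triggers and their arguments, and deterministic rule-based postprocessing —
with BRAT-style standoff I/O, evaluation at exact and relaxed span matching,
and a synthetic patent-snippet generator for controlled experiments.

## The problem

Chemical patents describe synthesis procedures in semi-regular prose:

> EXAMPLE 12 … The mixture was stirred at 50 ° C for 2 h … washed with
> sat. aq. NH4Cl … Yield: 15 mg (25% of theory).

The task is to recover, from raw text, (i) typed entity mentions over 12
labels — ten reaction roles (`EXAMPLE_LABEL`, `STARTING_MATERIAL`,
`REAGENT_CATALYST`, `REACTION_PRODUCT`, `SOLVENT`, `TIME`, `TEMPERATURE`,
`YIELD_PERCENT`, `YIELD_OTHER`, `OTHER_COMPOUND`) and two event triggers
(`REACTION_STEP`, `WORKUP`) — and (ii) trigger–argument relations, labeled
`ARG1` when the argument is a compound role and `ARGM` when it is a
time/temperature/yield modifier. The relation label is fully determined by
the argument's entity label.

## The model

The pipeline is a cascade:

1. **Preprocessing** — sentence segmentation with an abbreviation guard
   (`sat.`, `aq.`, …), punctuation-as-separator tokenization
   (`[\p{L}\p{N}]+` runs or single punctuation marks), and greedy
   longest-prefix subword alignment against a corpus-derived vocabulary with
   `##` continuation pieces.
2. **Sequence labeling** — BIO tagging (25 tags) with an averaged structured
   perceptron: per-token feature weights (surface, lowercase, word shape,
   prefixes/suffixes, punctuation class, a ±2 token window) plus first-order
   tag-transition weights, decoded with Viterbi. For a sentence
   `x₁…xₙ` the decoder maximizes `Σᵢ w·φ(xᵢ, yᵢ) + t(yᵢ₋₁, yᵢ)`.
3. **Relation extraction** — every within-sentence trigger × role pair is a
   candidate; both mentions are masked by their entity type and the pair is
   scored by ridge-penalized logistic regression over bag-of-masked-tokens,
   trigger-surface, argument-label, token-distance-bin and direction
   features; pairs with probability ≥ 0.5 become relations.
4. **Rules** — exhaustive patterns that repair systematic errors: trimming
   lead words from identifiers ("Example 95" → "95", "compound 1-0003" →
   "1-0003"), relabeling compounds in example headings, merging the faulty
   sentence split after "sat. aq." and linking the stranded compound to its
   trigger, and attaching "Yield: …" sentences to the preceding trigger.
   Every edit is recorded in a rule trace.

An optional majority-vote ensemble (`ensembleVote`) combines taggers trained
under different seeds, keeping mentions predicted by strictly more than half
of the models.

## Worked example

```r
library(ChemPatentIE)

tokenizePunct("7-Bromo-4-(pyridin-2-yl)-3,4-dihydro-2H-benzo(b) (1,4)oxazine (1)")
# 35 rows; the first few:
#   surface start end
# 1       7     0   1
# 2       -     1   2
# 3   Bromo     2   7
# 4       -     7   8

docs  <- generateCorpus(generatorConfig(nDocuments = 120, seed = 7))
model <- trainTagger(docs[1:100], taggerConfig(seed = 42, epochs = 5))
clf   <- trainRelationClassifier(docs[1:100], relationConfig(seed = 42))
pred  <- runPredict(pipelineConfig(), docs = docs[101:120],
                    artifacts = list(tagger = model, classifier = clf))
score(docs[101:120], pred, "ner", "exact")
# EvalReport: task ner, exact matching
#              label  tp fp fn precision recall     f1
#      EXAMPLE_LABEL  20  0  0    1.0000 1.0000 1.0000
#     OTHER_COMPOUND  43  8  4    0.8431 0.9149 0.8776
#   REACTION_PRODUCT  25  2  0    0.9259 1.0000 0.9615
#                ...
#            Overall 289 12  6    0.9601 0.9797 0.9698
score(docs[101:120], pred, "end_to_end", "exact")@overall$f1
# [1] 0.9834254
```

A command-line interface covering `generate`, `train`, `predict`, `evaluate`
and `run-all` is installed at `inst/scripts/chemu-pipeline.R`.

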