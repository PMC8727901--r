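---
title: "Methods: reaction information extraction from chemical patents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reaction information extraction from chemical patents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific design of **ChemPatentIE**: the task,
the model cascade, the synthetic corpus the package evaluates itself on,
every numerical choice and its rationale, and what the passing test suite
does and does not demonstrate.

## 1. Task

Chemical patents describe synthesis procedures ("EXAMPLE 12 … The mixture
was stirred at 50 ° C for 2 h … Yield: 15 mg (25% of theory)."). Structuring
them requires two coupled predictions over raw text:

* **Entity mentions** over 12 labels: ten reaction roles (`EXAMPLE_LABEL`,
  `STARTING_MATERIAL`, `REAGENT_CATALYST`, `REACTION_PRODUCT`, `SOLVENT`,
  `TIME`, `TEMPERATURE`, `YIELD_PERCENT`, `YIELD_OTHER`, `OTHER_COMPOUND`)
  and two event triggers (`REACTION_STEP`, `WORKUP`). Mentions are
  contiguous character spans in 0-based half-open code-point offsets,
  serialized in BRAT-style standoff (`T` lines; `R` lines for relations).
  The legacy spellings `REACTION_SETUP` and `WORK_UP` are normalized on
  input.
* **Relations** from a trigger to an argument in the same event. The label
  is determined by the argument role: `ARG1` for the five compound roles,
  `ARGM` for time/temperature/yield modifiers (`assignRelationLabel`).
  `EXAMPLE_LABEL` never takes part in relations.

## 2. Preprocessing

**Sentence segmentation** splits after `.`, `!`, `?` followed by whitespace
or end-of-text, and at newlines, unless the preceding token is a known
abbreviation (`sat.`, `aq.`, `approx.`, `conc.`, `vs.`, `e.g.`, `i.e.`,
`no.`, `fig.`). The guard is deliberately a small closed list: patent prose
is formulaic and an open-ended heuristic would be harder to audit. One
systematic failure survives by design — "sat. aq." at a line or clause edge
can still be split in noisy input — and is repaired downstream by a rule
(§5) rather than by complicating the segmenter.

**Tokenization** is two-stage. The first stage treats every punctuation
character as a separate token (`[\p{L}\p{N}]+|[^\p{L}\p{N}\s]`), because
chemical names are dense in hyphens, commas and brackets that carry
boundary information: "7-Bromo-4-(pyridin-2-yl)-3,4-dihydro-2H-benzo(b)
(1,4)oxazine (1)" yields 35 tokens. The second stage aligns each token
against a subword vocabulary by greedy longest-prefix matching with `##`
continuation pieces, falling back to `[UNK]`. The vocabulary
(`buildVocabulary`) contains an alphabet floor (every single character seen,
in both word-initial and `##` form, so alignment never dead-ends) plus the
most frequent character n-grams up to `maxPiece = 8` characters, capped at
`maxSize = 2000` entries with deterministic frequency-then-lexicographic
tie-breaking. 2000 comfortably covers the synthetic lexicon while keeping
the feature space small; `maxPiece = 8` captures morphemes like "pyridin"
without memorizing whole names.

## 3. Sequence labeling

Mentions are encoded as BIO tags (25 tags: `O` plus `B-`/`I-` per label).
The tagger is an **averaged structured perceptron** with first-order tag
transitions, decoded by Viterbi. For sentence $x_1\dots x_n$ it maximizes

$$\sum_i \big[ w \cdot \phi(x, i, y_i) + t(y_{i-1}, y_i) \big]$$

with features per token: surface form, lowercase form, word shape
(`Xx`, `d`, `-` classes), prefixes/suffixes up to length 3, a punctuation
indicator, and the same for a ±2 token window. A conditional random field
would be the textbook choice for this structured objective; no CRF
implementation is available in this environment, and the averaged
perceptron is a standard, well-understood substitute that optimizes the
same decoding objective with the same feature and transition structure,
differing only in the estimation procedure (error-driven updates with
parameter averaging instead of maximum likelihood). Training shuffles
sentences each epoch under a fixed seed and restores the caller's random
state; weight matrices have sorted row names so serialized models are
byte-identical across runs.

Defaults: `epochs = 5`, `window = 2`, `seed = 42`. Five epochs suffice at
the study scale of hundreds of documents; tiny corpora need more passes
(fewer updates per epoch — the unit tests use 20 epochs on 1–60 document
fixtures). Decoding repairs ill-formed tag sequences leniently (`I-X`
without a preceding `B-X` opens a new mention) rather than failing, since
downstream consumers need spans, not tags.

**Ensembling.** `ensembleVote` combines $k$ taggers trained under different
seeds, keeping mentions (label, start, end) predicted by strictly more than
$k/2$ models, then resolving residual overlaps by votes, earlier start,
longer span. Majority voting can only discard minority errors, which is why
the ensemble never scores below the worst single model on the same split —
a property the acceptance suite checks empirically.

## 4. Relation extraction

Candidates are all within-sentence trigger × role mention pairs
(`EXAMPLE_LABEL` excluded). Each candidate is rendered as a masked token
sequence — *all* entity mentions in the sentence replaced by their labels,
so the classifier cannot memorize chemical names — and featurized with:
bag of masked tokens, masked tokens between the pair, trigger surface,
argument label, token-distance bins (1, 2, 3, 4–5, 6–8, 9+), and direction.
The classifier is ridge-penalized logistic regression
(`glmnet`, `alpha = 0`, final `lambda = 1e-3`, `standardize = FALSE` since
features are sparse indicators); a pair becomes a relation when its
probability exceeds `threshold = 0.5`. Ridge rather than lasso because the
indicator features are heavily collinear and we want stable, dense
coefficients rather than feature selection; `1e-3` is light regularization
appropriate for thousands of training pairs. The predicted relation label
is then assigned deterministically from the argument role.

## 5. Rules

Rules are exhaustive, traceable patterns applied after the statistical
stages; each edit appends a record to the document's rule trace.

* `trimExampleLabel`: strips brackets/whitespace and lead words
  (*example, step, intermediate, core, reference example*) from
  `EXAMPLE_LABEL` spans — "Example 95" → "95". If trimming would empty the
  span the mention is left untouched and flagged with a warning trace.
* `trimCompoundPrefix`: removes *compound/example/immediate* lead words
  from compound mentions only when the remainder is a numeric-style
  identifier — "compound 1-0003" → "1-0003", but "sodium chloride" is
  never touched.
* `relabelHeadingCompounds`: compounds named in a top-level `EXAMPLE`
  heading are `OTHER_COMPOUND` (they name the target, not a participant);
  inside a numbered sub-step region the product line is
  `REACTION_PRODUCT`. This repairs the tagger's most systematic confusion.
* `mergeSatAqAndLink`: re-joins a sentence wrongly split after "sat. aq.",
  then links the stranded compound to a trigger. Two linking strategies are
  exposed because the right answer is genuinely underdetermined:
  `"nearest"` (default — the closest preceding trigger, correct when the
  wash clause names its own verb) and `"clause-head"` (the first trigger of
  the clause, for corpora where washes attach to the step verb). This is an
  open design decision, not a tuned constant.
* `linkYieldSentence`: a sentence matching `^Yield\s*:` attaches its yield
  mentions as `ARGM` to the last trigger of the previous sentence.

The synthetic generator emits gold annotations that are fixed points of all
rules, so idempotence (`applyNerRules(applyNerRules(d)) == applyNerRules(d)`)
is testable and rules can only repair, not corrupt, gold-consistent input.

## 6. Evaluation

Precision, recall and F1 with the zero-denominator convention (empty
prediction or gold set scores 0). Two matching modes: **exact** (label and
both offsets equal) and **relaxed** (label equal, spans overlap in at least
one character). Matching is one-to-one and greedy, largest overlap first;
the test suite verifies it against an exhaustive maximum-matching oracle on
randomized mention sets. Relations match when their label and both endpoint
entities match under the active mode. Relaxed can only add matches, so
relaxed F1 dominates exact F1 — asserted as a property test. Reports carry
per-label and overall rows and serialize to JSON.

## 7. Synthetic corpus

`generateCorpus` produces patent-like example records: an `EXAMPLE n`
heading, an optional numbered sub-step block (fraction 0.3), two reaction
sentences built from templated verb frames over a compositional IUPAC-like
name grammar (substituent–locant prefixes over heterocycle/core heads), a
workup sentence that with fraction 0.2 exercises the "sat. aq." phenomenon,
and a product sentence that with fraction 0.3 moves the yield into a
separate "Yield: …" sentence. All twelve labels and both relation labels
occur with stable frequencies by 50 documents. Generation is deterministic
under `seed` and restores the caller's random state.

The fractions are package choices, picked so every rule phenomenon appears
often enough to be trained and tested on (tens of instances per 100
documents) without dominating the corpus; they were fixed before the
acceptance thresholds were evaluated and are not tuned to the results. The
study sizes (500 train / 125 held-out) are likewise the package's own
choice: large enough that held-out scores are stable to ±0.01 across seeds,
small enough to train in about a minute on one CPU.

## 8. What the tests show — and what they don't

The suite demonstrates, on *this generator's distribution*: held-out exact
NER F1 ≥ 0.90 and end-to-end relation F1 ≥ 0.80 (measured ≈ 0.99 / 1.00),
metric correctness against exhaustive oracles, byte-identical retraining,
and rule behavior on worked examples. It does **not** demonstrate
performance on real patent text: the generator's lexical variety, OCR
noise, and discourse structure are far simpler than real patents, and the
near-ceiling scores should be read as "the cascade is implemented
correctly and learns this distribution", not as a claim about production
accuracy. Known limitations: mentions must be contiguous (discontinuous
standoff spans are rejected on read), relations are within-sentence except
for the yield rule, and offsets are code points — callers holding UTF-16
offsets must convert.
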