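Package: ChemPatentIE
Title: Chemical Reaction Information Extraction from Patent Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for extracting chemical reaction
    information from patent text snippets: punctuation-separator
    tokenization with greedy subword alignment, BIO sequence labeling of
    ten semantic roles and two event-trigger types, trigger-argument
    relation extraction with entity-type masking, deterministic
    rule-based postprocessing, majority-vote ensembling, and exact and
    relaxed span-matching evaluation. Includes a reader and writer for
    BRAT-style standoff annotation and a synthetic corpus generator of
    templated reaction paragraphs so the whole cascade can be trained
    and scored without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
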