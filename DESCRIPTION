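Package: phenoseg
Title: Two-Phase Hybrid Segmentation of Skeletal Phenotype Descriptions
Version: 0.1.0
Authors@R:
    person("Phenoseg", "Developers", email = "phenoseg@example.org",
           role = c("aut", "cre"))
Description: Decomposes free-text skeletal phenotype descriptions (such as
    Human Phenotype Ontology term labels) into their atomic anatomical and
    quality elements. Phase I segments a description into anatomy, quality
    and connective entities with BIO sequence labeling; phase II splits each
    entity into quality-qualifier pairs or anatomy main-part / sub-part /
    coordinate structure. Segmentation is performed by an ensemble of four
    divergent sequence labelers (two global Viterbi-decoded models and two
    greedy chunkers in one-vs-one and one-vs-all multiclass modes),
    aggregated by set operations or veto-based majority voting. Includes
    gazetteer and morphological feature engineering, a CoNLL-style corpus
    reader/writer, stratified k-fold cross-validation with token-level
    precision/recall/F1, and a synthetic-corpus generator so the full
    pipeline is testable without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
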