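# phenoseg

Two-phase hybrid segmentation of skeletal phenotype descriptions.

## The problem

Phenotype ontologies such as the Human Phenotype Ontology (HPO) carry most
of their meaning in free-text term labels like *Irregular, flared
metaphyses of the long bones with streaky sclerosis*. Downstream work in
the Entity–Quality (EQ) formalism — aligning phenotypes to FMA anatomy and
PATO qualities, building anatomical-localization decision support —
requires those labels decomposed into their atomic elements. `phenoseg`
performs that decomposition for the skeletal phenotype domain in two
phases:

* **Phase I** labels each token of a description with a BIO tag over three
  coarse classes — **A**natomy, **Q**uality, **C**onnective (plus **O**
  outside) — and joins maximal `X-B (X-I)*` runs into entities.
* **Phase II** re-segments each entity with a class-specific tagger:
  anatomical entities into main concept (`A`), sub-parts (`AP`),
  single-token anatomical coordinates (`PB`) and connectives (`C`);
  quality entities into qualities (`Q`) and qualifiers (`QF`).

So *irregular flared metaphyses of the long bones with streaky sclerosis*
becomes qualities *irregular*, *flared* and *sclerosis* (qualifier
*streaky*), and an anatomical entity whose main concept is *long bones*
with sub-part *metaphyses*.

## The method

Segmentation is performed by an **ensemble of four divergent sequence
labelers** behind one contract: two global models (averaged structured
perceptrons with first-order transitions and Viterbi decoding, the CRF
family of taggers) and two greedy left-to-right chunkers (averaged
perceptrons over the feature window with the two previous predicted labels
as dynamic features) in genuine one-vs-one and one-vs-all multiclass
modes. Divergence also comes from distinct context windows (2/3) and
affix sizes (4/5) per member.

Each token is described by the classical feature inventory of biomedical
NER: token/lemma/base/POS/category, orthographic shape and brief shape,
uni/bi/tri-gram contexts with `@` padding, punctuation/digit/vowel
patterns, prefixes and suffixes of increasing length, six gazetteer flags
(conjunctions, connections, coordinates, ordinals, anatomy, qualities) and
nine combined context × dictionary × base features.

Member outputs are sets of `(position, label)` assignment pairs,
aggregated by

* **set operations** — union (recall up, precision down), intersection
  (the reverse), and the combined form
  `intersection(union(a, b), union(c, d))`; or
* **simple majority voting with veto** — per token: ≥3 agreeing votes win;
  2 agreeing votes win if the other two contradict each other; a 2–2 tie
  or four distinct votes falls to the designated veto owner's own vote.

Evaluation is token-assignment-level precision/recall/F1 (micro and
per-label, in percent) under ten-fold stratified cross-validation. A
one-label-per-position strategy (single member, voting) necessarily has
micro P = R = F; unions trade precision for recall — the package asserts
both structural facts in its test suite.

Because the original annotated HPO corpus is not redistributable, the
package ships a **synthetic-corpus generator**: a template grammar over
the field's vocabulary (qualifier–quality clauses, coordinate / part /
"of the" / main anatomical phrases, rare connective clauses and temporal
tails, atomic phenotypes labeled wholly as qualities) calibrated so the
phase I label-category shares approximate the reference distribution
(anatomy ≈ 70%, quality ≈ 29.5%). The generator tracks fine-grained
labels per token, so both phase II corpora are derived mechanically with
entity de-duplication.

## Worked example

```r
library(phenoseg)

resources <- synthetic_resources()
corpus <- generate_phase1(grammar_config(n_descriptions = 1000, seed = 7))
phase2 <- derive_phase2(corpus)

# train the default four-member ensemble for phase I
members <- lapply(make_default_ensemble("1", seed = 7),
                  train_labeler, corpus = corpus, resources = resources)
models <- list(
  phase1  = list(members = members, spec = aggregation_spec("voting")),
  anatomy = train_labeler(phase2$anatomy,
                          make_default_ensemble("anatomy")$crf_a, resources),
  quality = train_labeler(phase2$quality,
                          make_default_ensemble("quality")$crf_a, resources))

decompose(
  "irregular flared metaphyses of the long bones with streaky sclerosis",
  models, resources)
```

prints

```
<decomposed_phenotype> irregular flared metaphyses of the long bones with streaky sclerosis
  quality: irregular
  quality: flared
  quality: sclerosis  [qualifiers: streaky]
  anatomy: long bones  [parts: metaphyses]
```

i.e. three quality groups (the third pairing the qualifier *streaky* with
the quality *sclerosis*) and one anatomy group whose main concept is
*long bones* with sub-part *metaphyses*. `decompose_to_json()` serializes
the same structure.

Cross-validating the voting ensemble on the synthetic corpora:

```r
cv <- cross_validate(corpus, make_default_ensemble("1", seed = 7),
                     aggregation_spec("voting", veto_owner = "svm_1vsall"),
                     resources, k = 10, seed = 7)
cv$average$micro
#> precision    recall        f1
#>  99.81563  99.81563  99.81563
```

(micro P = R = F is exact for voting, by construction). The same
command-line workflow is available through `inst/cli/phenoseg.R`
(`gen-corpus`, `train`, `cv`, `decompose`).

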