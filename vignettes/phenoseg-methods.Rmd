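---
title: "Methods: two-phase hybrid segmentation of skeletal phenotype descriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase hybrid segmentation of skeletal phenotype descriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`phenoseg` treats the decomposition of a skeletal phenotype description as
two successive BIO sequence-labeling problems.

**Phase I** labels every token with one of `A-B, A-I, Q-B, Q-I, C-B, C-I,
O`: coarse anatomical entities, qualities, connectives, and outside
tokens. Atomic phenotypes (terms such as *acromelia* whose entity–quality
structure is implicit) are labeled wholly as qualities: they bear a
qualitative purpose even though they are not qualities in the strict
ontological sense, and this keeps them available for qualifier–quality
pairing in phase II. Maximal runs `X-B (X-I)*` are then joined into
entity segments and partitioned by class (qualities first, then anatomy,
then connectives — the output ordering is a convention of this package).

**Phase II** runs a class-specific tagger *inside* each segment, never
across segment boundaries. Anatomical entities are split over `A-B, A-I`
(main concept), `AP-B, AP-I` (sub-part), `PB` (anatomical coordinate),
`C-B, C-I` (internal connectives like *of the*) and `O`. Coordinates are
single tokens by assumption, so `PB` has no continuation label; conjoined
coordinates (*proximal and distal*) are separate `PB` tokens linked by a
connective. Quality entities are split over `Q-B, Q-I` (quality),
`QF-B, QF-I` (qualifier), `C-B, C-I`, `O`.

Token spans are 0-based and half-open throughout. Tokenization is
whitespace splitting with `, . ; : ( )` detached into their own tokens;
hyphens and slashes stay inside tokens so metaphorical multi-hyphen terms
(*bone-in-bone*) and ordinals (*1st*) survive as single tokens.

Invalid BIO transitions are treated asymmetrically: in gold corpora they
are errors (optionally repairable on read), while in predicted output an
orphan `X-I` is always silently promoted to `X-B` — classifiers may emit
them and a total, legal labeling is part of the prediction contract.

## The ensemble

Four divergent labelers are trained per task:

| member       | family              | decoding            | window | affix |
|--------------|---------------------|---------------------|--------|-------|
| `crf_a`      | global (structured) | Viterbi             | 2      | 4     |
| `crf_b`      | global (structured) | Viterbi             | 3      | 5     |
| `svm_1vs1`   | greedy chunker      | left-to-right       | 2      | 5     |
| `svm_1vsall` | greedy chunker      | left-to-right       | 3      | 4     |

The environment this package targets has no CRF toolkit and no SVM
library, and the ensemble design does not depend on either: what matters
is that the members make *different* errors. The global family is an
averaged structured perceptron with first-order transition weights —
like a CRF it scores whole label sequences and decodes with Viterbi. The
chunker family classifies tokens left to right with the two previous
predicted labels as dynamic features, using averaged binary perceptrons
in two genuinely different multiclass constructions: one-vs-one (pairwise
classifiers, vote counting, ties broken by summed margin then label
order) and one-vs-all (per-label classifiers, argmax margin). All four
are deterministic given their seed: example order is the only stochastic
element, weights are lazily averaged, and every argmax breaks ties by
canonical label order. Training stops early once an epoch makes no
mistakes (the default cap is 8 epochs).

Only the forward (left-to-right) chunker direction is implemented; a
backward variant adds nothing on this task and is out of scope.

## Features

The per-token inventory is the classical biomedical NER set: token,
lemma, lexical base, POS tag, lexical category, orthographic shape
(`A`/`a`/`0` map) and its run-length-collapsed brief shape, uni-/bi-/
tri-gram contexts over a `@`-padded window, trailing-punctuation flag,
digit pattern (digit-free tokens yield the literal `"no"`, mirroring the
flag convention of the dictionary features), vowel pattern (vowels are
`a e i o u`; `y` is not a vowel), prefixes and suffixes of increasing
length, six gazetteer membership flags, and nine combined features
(base × domain dictionary, context × domain dictionary, context over
bases, context over bases × domain dictionary).

Two definitions deserve a note:

* **n-gram contexts** are defined self-consistently as the contiguous
  n-grams over the same padded window the unigram feature uses, giving
  `2w + 2 - n` values for order *n*. Published examples of such features
  sometimes mix window conventions between their unigram and bigram
  illustrations; the self-consistent definition is implemented and
  asserted (`|uni| = 2w + 1`, `|bi| = 2w`, `|tri| = 2w - 1`).
* **Sequence edges** pad with `@` for every order, so position 0 still
  has a full-width feature vector.

Gazetteer lookups in context features are token-aligned: a multi-word
gazetteer term also indexes its constituent tokens, since all context
flags are per-position. Strict whole-term membership is available
separately (`member_flag()`).

Lemma and POS come from a pluggable tagger interface. The bundled
implementation is a deterministic rule set (closed-class lists plus
suffix rules) — adequate as a stable fixture, and deliberately not a
claim about linguistic accuracy; real taggers used on this kind of data
are imperfect too, and exact tagger parity is a non-goal. The lexical
base falls back, for surfaces missing from the lexical table, to a fixed
suffix-stripping table (`-yses→-ysis`, `-oses→-osis`, `-s`, `-ed`,
`-ing`) so tests are deterministic without an external lexicon.

Ablation is structural: disabling the domain dictionaries removes exactly
the two domain-dictionary flags and the nine combined features and
nothing else; phase II tasks never use them, and the quality task also
drops the coordinates and ordinals dictionaries.

## Aggregation semantics

Set operations act on `(position, label)` **assignment pairs**, not on
whole segments. This is a deliberate and load-bearing choice: under it, a
single labeler (or the voting scheme) emits exactly one pair per
position, which forces micro precision = recall = F1 exactly, while a
union can place two labels on one position (precision down, recall up)
and an intersection can leave a position empty (the reverse). Those
structural identities and inequalities are asserted in the test suite;
segment-level scoring would not produce them.

In voting, consensus is per token: three or four agreeing votes win; two
agreeing votes win when the other two members contradict *each other*; a
2–2 tie between distinct pairs, or four distinct votes, falls to the
veto. The veto is resolved by adopting the veto owner's own vote — the
only resolution consistent with reporting per-owner results. The
implementation is verified against an independent enumeration oracle on
all 7⁴ vote tuples for each veto owner.

When a set-operation strategy is used end to end, positions left with no
label become `O` and positions with two labels resolve by class priority
anatomy > quality > connective > outside (anatomy dominates the corpus at
roughly 70% of tokens), preferring `B` over `I` within a class, followed
by BIO repair. Voting and single strategies never need this rule. The
default bracket composition for combined aggregation pairs each chunker
with a different global model: each union bracket then mixes error
profiles, and the final intersection prunes bracket-specific false
positives.

## Evaluation

Metrics are token-assignment-level micro and per-label P/R/F1 in percent.
Cross-validation is ten-fold with stratification at the description
level, targeting the distribution of label categories (A/Q/C/O): a
greedy balancer assigns descriptions largest-first, keeps fold sizes
within one of each other, fills folds in lock-step (only minimum-size
folds accept the next description, so runs of similar descriptions
spread across folds), and within a round picks the fold whose category
proportions the description improves most. Fold averages are unweighted
means; per-label figures are averaged per fold rather than pooled
(either convention is defensible; the per-fold mean matches how the
micro scores are averaged).

## The synthetic corpus

The generator is a template grammar over this field's vocabulary:
`[qualifier] quality` clauses (optionally two), an anatomical phrase that
is either `[coordinate [conj coordinate]] part "of the" main` or
`[coordinate] main`, a rare trailing `with <quality>` clause (the
connective class), a rare temporal tail (*in first year*, labeled `O`),
and occasional atomic phenotypes labeled wholly as qualities. The slot
probabilities are calibrated once so that the phase I label-category
shares approximate the reference corpus distribution — anatomy ≈ 70%,
quality ≈ 29.5%, connectives and outside each ≈ 0.2% — and are not
revisited; at n = 1000 the generated shares sit within a fraction of a
point of the targets (asserted at ±5 points). Connectives and outside
tokens are therefore *deliberately* nearly unlearnable at this scale,
matching the reference setting where those labels score far below the
dominant ones.

Hard cases are planted: *radial* appears both in the coordinates
vocabulary and inside the multi-token main *radial club hand*, so the
taggers must use context rather than the gazetteer; metaphors are
single hyphenated tokens; atomic phenotypes have no anatomical anchor.
Fixture gazetteers are generated jointly with the grammar but with every
fourth term dropped, and the lexical table covers only part of the
vocabulary — dictionary features are informative yet incomplete, which
is why enabling or disabling the domain dictionaries barely moves the
cross-validated score (asserted at ≤ 2 points).

What a green test does **not** establish: the grammar is far more
regular than curated ontology labels (no nested anatomy chains such as
*epiphyses of the phalanges of the hand*, no spelling variation, no
annotation noise, a vocabulary of dozens rather than thousands), so the
cross-validated scores on it (≥ 95 phase I, ≥ 90 phase II, at fixed
seed) are a recovery check of the machinery, not an estimate of
performance on real ontology corpora — the published scores on the real
corpus are in the 94–97 range and are not reproducible without it.
Generation, training and folding are deterministic given their seeds.

The phase II corpora are derived from phase I output by extracting A and
Q segments, relabeling through the generator's per-token bookkeeping,
and de-duplicating by exact segment text, so repeated entities are
retained once.

## Numerical choices and degenerate inputs

* All tie-breaks (Viterbi, argmax, vote counting, fold choice) resolve to
  the first candidate in canonical order; no randomness at predict time.
* Training on a corpus with a single label class warns and returns a
  constant predictor.
* Empty token sequences predict empty assignment sets; empty gold in
  scoring warns and reports recall 0.
* Scores are percentages in [0, 100]; F1 is the harmonic mean, 0 when
  both P and R are 0.
* Unseen features at predict time are dropped (zero weight); the feature
  dictionary is string-keyed, so member models never collide.

## Known limitations

* No alignment of segments to ontology concept identifiers (FMA/PATO/
  HPO); segmentation output is text spans.
* No post-processing heuristics beyond BIO repair, by design.
* No weighted or confidence-based voting; the scheme is unweighted with
  a veto.
* Qualifier–quality association across separate phase I segments is out
  of scope (phase II is strictly intra-segment).
* The bundled tagger and stemmer are deterministic fixtures, not
  linguistic tools; swap in a real tagger through the resources
  interface for production use.
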