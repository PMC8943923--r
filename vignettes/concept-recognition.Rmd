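---
title: "Parallel concept recognition: flattening, harmonisation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel concept recognition: flattening, harmonisation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paratag)
```

## The problem

Concept recognition in biomedical text combines two tasks: finding the
mentions (named-entity recognition) and grounding each mention in an
ontology concept (normalisation).  Reference corpora such as CRAFT anchor
their annotations in standoff format, which permits *discontinuous*
mentions (one concept realised by several non-adjacent fragments, as in
"ES ... cells" inside "ES and somatic cells"), *overlapping* mentions, and
*sub-word* mentions.  Token-level sequence taggers, by contrast, consume a
verticalised (CoNLL-style) view in which every token carries exactly one
label per channel.  The gap between the two representations is real
information loss, and managing that loss — and the disagreements between
parallel prediction channels — is what this package implements.

The pipeline has three stages, each usable on its own:

1. **Flattening** (`encode_labels()` / `decode_entities()`): standoff
   annotations become IOBES span tags plus a concept-ID tag per token, and
   back.
2. **Parallel tagging** (`dict_tag()`, `train_memorisation()` /
   `predict_memorisation()`, or imported predictions via `read_conll()`):
   three channels per token — span tag, concept-ID tag, dictionary
   features.
3. **Harmonisation** (`harmonise()`): the channels are merged into one
   final annotation set under one of four rule-based strategies, scored by
   a similarity-weighted evaluator (`evaluate()`).

## Flattening and its strategies

Two label sets are written per token: IOBES span tags (`B`/`I`/`E` for
multi-token entities, `S` for single-token entities, `O` outside) and a
concept-ID channel in which entity tokens carry the concept ID and all
others carry the reserved `NIL` label.  `NIL` and `O` can therefore never
be concept IDs; the constructors reject them.

Because one label per token cannot express discontinuity or overlap, gold
annotations are simplified before encoding:

* **Unification** collapses a discontinuous annotation to one contiguous
  span: `first-span` keeps the first fragment, `last-span` the last,
  `full-span` stretches across all fragments.  Contiguous annotations are
  unaffected by all three.
* **Unnesting** removes overlaps: `keep-longer` prefers the longer of two
  overlapping annotations, `keep-shorter` the shorter.  With more than two
  mutually overlapping candidates the pairwise preference is generalised
  greedily: candidates are sorted by length in the preferred direction,
  then by start offset, then by lexically lowest concept ID, and accepted
  whenever they overlap nothing already accepted.  The tie-breaks are a
  design choice of this package; only the pairwise preference is inherent
  to the strategy names.
* **Sub-word extension** grows any span to the token boundaries it
  touches.

The pipeline order is unify → snap-to-tokens → unnest.  The order between
the first two and the last is a genuine design decision: snapping can
*create* overlaps (two sub-word annotations inside one token), so
unnesting must run after it to guarantee a single label per token.

On the worked coordination example (`coordination_example()`) the six strategy
combinations produce four distinct flattened sets, three of which have
lost one of the two annotations entirely — the canonical illustration
that flattening is lossy:

```{r coordination}
fx <- coordination_example()
tok <- tokenize(fx$doc)
for (u in c("first-span", "full-span", "last-span")) {
  for (n in c("keep-longer", "keep-shorter")) {
    flat <- flatten_annotations(fx$annotations, strategy_config(u, n), tok)
    cat(sprintf("%-11s %-12s -> %s\n", u, n,
                paste(sprintf("%s[%d,%d)", flat$concept_id, flat$start,
                              flat$end), collapse = " ")))
  }
}
```

Decoding (`decode_entities()`) is strict by default: `S` must stand alone,
`B`...`E` must carry a uniform non-NIL ID, and `O` must coincide with
`NIL`; any violation is an error naming the token.  Predicted sequences
are rarely well-formed, so a repair mode normalises them
deterministically: a stray `I`/`E` opens an entity, an entity closes
before `O` or `S`, and an ID change inside an entity splits it at the
change point.  A non-NIL ID under an `O` span tag is honoured only where
the caller opts into ID-driven decoding (harmonisation backoff does;
plain decoding does not).

## Harmonisation

Each token is judged relevant or not by three channels independently —
span tag ≠ `O`, ID ≠ `NIL`, dictionary features non-empty — giving
`2 × 2 × 2 = 8` disagreement patterns (`relevance_pattern()`).  The four
strategies resolve them with a fixed bias:

* `spans-only` trusts the span channel for boundaries and the dictionary
  for labels: each decoded span entity takes the ID of its
  best-overlapping dictionary match (character-level Jaccard, ties broken
  by the lexically lowest ID).  A concept label is always required, so
  span entities without any supporting dictionary match are dropped.  The
  ID channel is ignored.
* `ids-only` trusts the ID channel alone: maximal runs of identical
  non-NIL IDs become annotations, even where the span channel says `O`.
  The dictionary is ignored.
* `spans-first` applies `spans-only`, then backs off to `ids-only` on the
  tokens the former left unclaimed; `ids-first` is the mirror image.

Two points in the backoff were genuinely open and are fixed here as
package design choices.  First, the backoff operates at *token*
granularity with *entity-level* ID assignment: an `ids-only` entity that
collides with an already-accepted entity is truncated to its unclaimed
contiguous token runs (keeping its ID) rather than dropped wholesale.
Second, under `ids-first` a truncated span-channel remnant must again find
an overlapping dictionary match, and its ID is re-selected on the remnant
span — labels are never carried past the evidence that supported them.
Confidence-score-based mixing strategies are deliberately out of scope.

Two structural properties follow from the construction and are enforced
by tests: the base strategies are contained in their backoff variants
(`spans-only` ⊆ `spans-first`, `ids-only` ⊆ `ids-first`), and when all
three channels derive consistently from the same gold, all four
strategies return exactly the flattened gold.

## Evaluation

Predictions are aligned to references greedily.  Every pair with textual
overlap is a candidate; its similarity is

* `j` — character-level Jaccard of the covered offsets,
* `c` — concept similarity: 1 for identical IDs, otherwise the Jaccard of
  the two concepts' self-inclusive `is_a` ancestor sets,
* `m = j · c`.

Candidates are sorted by `m`, then `j`, then reference and prediction
start, and accepted while both members are unused.  Each accepted pair
adds `m` to the match count and `1 − m` to the substitution count;
leftovers are deletions (reference side) or insertions (prediction side).
From the counts: `P = M/(M+S+I)`, `R = M/(M+S+D)`, `F` the harmonic mean,
and `SER = (S+I+D)/(M+S+D)`.

Three of these choices deserve justification:

* **`m` as a product.**  The definition guarantees `m = 1` exactly for a
  perfect prediction and `m = 0` when either component vanishes, and
  keeps `m ≤ j` and `m ≤ c`.  No byte-level parity with any external
  evaluation suite is claimed.
* **Ancestor-set Jaccard for `c`**, without depth weighting: a concrete,
  auditable instantiation of hierarchy-aware similarity; depth or
  information-content weighting is a documented extension point.
* **Greedy rather than optimal assignment**: deterministic and
  `O(n² log n)`.  The test suite compares the greedy match mass against a
  brute-force optimal assignment on instances with up to six annotations
  per side; greedy is the specified behaviour and carries the classic
  factor-2 guarantee for greedy weighted matching, and on the generated
  instances the observed gap is essentially zero.

Degenerate inputs follow fixed conventions: with neither references nor
predictions, `P = R = F = 1` and `SER = 0`; with predictions against an
empty reference, `P = R = F = 0` and `SER` is undefined and reported as
`NA` rather than a number.  Pairs require `j > 0` but not `c > 0`, so a
wrong-ID prediction on the right text counts as a substitution, not an
insertion/deletion pair.  Overlapping annotations within one side are an
input error: this evaluator scores flattened sets only.

The **unseen-concept protocol** (`filter_unseen()`) restricts both the
reference and the predictions to concept IDs absent from the training
annotations.  Two structural facts are then checkable without any trained
model: an example-based ID tagger can never contribute predictions to
this evaluation (its label set is contained in the training IDs), and
`spans-only` and `spans-first` become indistinguishable, because they
differ only through the ID backoff that the filter removes.

## Taggers at desk scale

The dictionary tagger matches token n-grams exactly after normalisation
(lower-casing, punctuation to spaces, whitespace collapse).  Fuzzy
matching in dictionary-based recognisers is approximated by that
normalisation alone, which keeps every match auditable and every test
exact; nested and overlapping matches are all reported, and ambiguity is
preserved as multiple candidate IDs per match.

The memorisation tagger is *not* a reimplementation of a neural
classifier; it is the minimal example-based stand-in that reproduces the
structural property the analysis depends on — it can only ever predict
concept IDs seen in its training data.  It memorises normalised flattened
gold surfaces with ID frequencies (flattening uses first-span /
keep-longer by default) and predicts by greedy longest match, emitting
the most frequent ID with lexically-lowest tie-breaking.  Real
token-level predictions from any external tagger can be imported through
`read_conll()` and harmonised unchanged.

`corrupt_labels()` generates controlled channel disagreement: per
channel, independently and under a fixed seed, entities are dropped,
relabelled within the label set, or have one boundary shifted by one
token.  It is the instrument behind the harmonisation property tests.

## The synthetic generator

`gen_ontology()` builds a rooted acyclic `is_a` graph whose concept names
reuse a small pool of head words ("cell", "kinase", ...), so that
two-word terms share heads.  That makes the two structurally hard cases
plantable by construction: a coordination `"X and Y Z"` carrying a
discontinuous annotation (`X ... Z`) that overlaps a contiguous one
(`Y Z`), and a nested shorter term (`Z` alone) inside a longer mention.
`gen_corpus()` assembles documents from filler-word sentences with
planted mentions, controlled by `corpus_spec()`: mention rate,
discontinuity / overlap / ambiguity probabilities, and the fraction of
concepts reserved for the test split.  The reservation is exact: with
fraction `f`, exactly `ceiling(f · n_used)` of the concepts appearing in
the corpus occur only in the test gold.

Default conditions (4 documents per split, 5 sentences per document,
1.2 mentions per sentence, 10% discontinuous, 15% overlapping, 10%
ambiguous surfaces) were chosen once to mirror the qualitative profile of
richly annotated full-text corpora — complex cases present but not
dominant — and are deliberately small enough that the whole suite runs in
seconds.  The property and acceptance tests use corpora of one to four
documents with three to five sentences, 15–30 concepts per ontology, and
50–200 replicates per property; these sizes are the package's own test
design, chosen so each property sees hundreds of independent instances.

What the generator does *not* emulate: real biomedical morphology and
tokenisation quirks, Zipfian concept frequencies, sub-word gold spans,
cross-sentence mentions, and annotator disagreement.  Passing tests
therefore demonstrate the algebra of the pipeline — losslessness where
losslessness is claimed, containment, exactness of the protocols — not
performance on real corpora.

## Known limitations

* Exactly one standoff dialect (brat-style, 4 tab-separated fields) and an
  OBO 1.2 subset (`is_a` only) are parsed; Knowtator XML, OWL and brat
  events/relations are out of scope.
* The evaluator requires flattened (non-overlapping) annotation sets on
  both sides and is not a byte-level replica of any official scoring
  suite.
* The tokeniser (alphanumeric runs plus punctuation singletons) is fixed;
  taggers trained on other tokenisations must be imported at the token
  level via CoNLL.
* Neural training, ontology pretraining and abbreviation expansion are
  intentionally absent; the package harmonises and evaluates predictions,
  it does not learn them.
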