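# paratag

Concept recognition in biomedical text — finding ontology-term mentions
and grounding them in concept IDs — is usually split across parallel
components: a span tagger (where is the mention?), an ID tagger (which
concept?), and a dictionary-based recogniser (which ontology terms match
here?).  `paratag` implements the machinery around such systems as a
reusable R framework:

* **Lossy flattening** between standoff annotations (brat-style, with
  discontinuous and overlapping mentions) and token-level IOBES /
  concept-ID label sequences, with selectable *unification* strategies for
  discontinuous mentions (`first-span`, `full-span`, `last-span`) and
  *unnesting* strategies for overlaps (`keep-longer`, `keep-shorter`),
  plus sub-word extension to token boundaries.
* **Three prediction channels**: an exact-matching dictionary tagger over
  OBO ontologies, a memorisation tagger that reproduces the structural
  constraint of example-based classifiers (it can only predict concept IDs
  seen in training), and import of any external tagger's token-level
  predictions via a CoNLL dialect.
* **Harmonisation** of the channels into one annotation set under four
  rule-based strategies: `spans-only`, `ids-only`, `spans-first`,
  `ids-first`.
* **Similarity-weighted evaluation**: aligned pairs score
  `m = j · c` where `j` is the character-level Jaccard overlap and `c` the
  Jaccard of the concepts' self-inclusive `is_a` ancestor sets; `m` counts
  toward matches `M`, `1 − m` toward substitutions `S`, and with
  insertions `I` and deletions `D`,
  `P = M/(M+S+I)`, `R = M/(M+S+D)`, `F = 2PR/(P+R)`,
  `SER = (S+I+D)/(M+S+D)`.  An unseen-concept protocol filters both sides
  to concepts absent from training.
* **Seeded synthetic generators** for ontologies and annotated corpora
  (including coordination mentions like "ES and somatic cells", nested
  overlaps, ambiguous surfaces, and an exact test-only concept
  reservation), so everything is testable without downloads.

See the methods vignette (`vignettes/concept-recognition.Rmd`) for the
model, the design decisions and the limitations.

## Worked example

Generate a corpus, derive the three channels, damage the span channel,
and watch the backoff strategies recover what the base strategies lose:

```r
library(paratag)

ont <- gen_ontology(20, seed = 42)
lex <- build_lexicon(ont)
cp  <- gen_corpus(ont, corpus_spec(n_docs = 2, sentences_per_doc = 3,
                                   p_discontinuous = 0, p_overlap = 0.3,
                                   p_ambiguous_surface = 0, seed = 7))
e      <- cp$train[[1]]
tokens <- tokenize(e$doc)
lab    <- encode_labels(e$doc, e$annotations)       # gold-derived channels
head(lab[, c("surface", "span_tag", "id_tag")], 7)
#>   surface span_tag      id_tag
#> 1  during        O         NIL
#> 2    show        O         NIL
#> 3 gozeldu        B SYN:0000016
#> 4    cell        E SYN:0000016
#> 5   study        O         NIL
#> 6   depax        S SYN:0000009
#> 7      in        O         NIL

tagged <- dict_tag(e$doc, tokens, lex)              # dictionary channel
noisy  <- corrupt_labels(lab, p_drop = 0.5, seed = 3)  # damage spans
input  <- labelled_tokens(tokens, span_tag = noisy$span_tag,
                          id_tag = lab$id_tag, dict = tagged$features)
for (s in c("spans-only", "ids-only", "spans-first", "ids-first")) {
  pred <- harmonise(input, tagged$matches, s, doc = e$doc)
  cat(sprintf("%-11s: %d annotations  ", s, length(pred)))
  print(evaluate(e$annotations, pred, ont)$metrics)
}
#> spans-only : 2 annotations  P=1.0000 R=0.5000 F=0.6667 SER=0.5000
#> ids-only   : 4 annotations  P=1.0000 R=1.0000 F=1.0000 SER=0.0000
#> spans-first: 4 annotations  P=1.0000 R=1.0000 F=1.0000 SER=0.0000
#> ids-first  : 4 annotations  P=1.0000 R=1.0000 F=1.0000 SER=0.0000
```

The span channel lost half its entities (`p_drop = 0.5`), so `spans-only`
recalls only half the gold (R = 0.50, SER = 0.50); the intact ID channel
lets `ids-only` and both backoff strategies restore a perfect score.
Which strategy wins is data-dependent — a corrupted ID channel inverts the
picture — which is why the strategy is a configuration value, not a
constant.

A shell entry point wrapping the same functions ships in
`inst/scripts/paratag`:

```sh
Rscript inst/scripts/paratag simulate --seed 4 --out /tmp/sim
Rscript inst/scripts/paratag roundtrip --in /tmp/sim/train \
        --ontology /tmp/sim/ontology.obo --unify first --unnest longer
```

with subcommands `convert`, `tag`, `harmonise`, `evaluate`, `simulate` and
`roundtrip` (standoff → CoNLL → standoff, scored against the input — the
upper bound a flattened representation imposes).

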