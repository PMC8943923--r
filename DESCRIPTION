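Package: paratag
Title: Parallel Concept Recognition with Lossy Flattening, Prediction
    Harmonisation and Ontology-Aware Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A framework for ontology-based concept recognition in
    biomedical text. Converts standoff annotations (including
    discontinuous and overlapping mentions) to token-level IOBES/ID
    label sequences and back, with selectable unification and unnesting
    strategies; runs parallel prediction channels (a dictionary-based
    ontology term tagger, a memorisation sequence tagger, and imported
    token-level predictions); harmonises the span-tag, concept-ID and
    dictionary channels into a single annotation set under four
    rule-based strategies; and scores predictions with
    similarity-weighted matches (character-level Jaccard times
    ontology-hierarchy similarity), F-score and slot error rate,
    including an unseen-concept evaluation protocol. Ships seeded
    generators for synthetic ontologies and annotated corpora so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
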