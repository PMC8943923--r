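# Shared fixtures and oracles, built in code.

# A tiny fixed ontology: root R, parent P with siblings X and Y, and a
# disjoint-tree concept Z (own root Q).
tiny_ontology <- function() {
  ontology(ids = c("T:R", "T:P", "T:X", "T:Y", "T:Q", "T:Z"),
           names = c("root", "parent", "xcon", "ycon", "qroot", "zcon"),
           parents = list(character(), "T:R", "T:P", "T:P", character(), "T:Q"))
}

# Contiguous single-span annotation shorthand.
flat_ann <- function(id, concept, start, end) {
  annotation(id, concept, c(start, end),
             text = paste0("t", start)) # placeholder text
}

# Random pairwise non-overlapping single-span annotation set on a line of
# `len` characters.
random_ann_set <- function(n, len, ids, prefix) {
  if (n == 0L) return(list())
  cuts <- sort(sample.int(len - 1L, min(2L * n, len - 1L)))
  out <- list()
  k <- 1L
  while (length(out) < n && k + 1L <= length(cuts)) {
    out[[length(out) + 1L]] <-
      flat_ann(sprintf("%s%d", prefix, length(out) + 1L),
               sample(ids, 1L), cuts[[k]], cuts[[k + 1L]])
    k <- k + 2L
  }
  out
}

# Brute-force maximum total match mass over all one-to-one alignments of
# reference and prediction annotations (pairs restricted to j > 0), used as
# the independent oracle for the greedy alignment.
optimal_match_mass <- function(reference, predictions, ont) {
  nr <- length(reference)
  np <- length(predictions)
  m <- matrix(0, nrow = nr, ncol = np)
  for (r in seq_len(nr)) {
    for (p in seq_len(np)) {
      j <- char_jaccard(reference[[r]]$spans, predictions[[p]]$spans)
      if (j > 0) {
        m[r, p] <- j * concept_similarity(reference[[r]]$concept_id,
                                          predictions[[p]]$concept_id, ont)
      } else {
        m[r, p] <- -1 # pair not admissible
      }
    }
  }
  best <- function(r, free_p) {
    if (r > nr) return(0)
    res <- best(r + 1L, free_p) # leave r unmatched
    for (p in free_p) {
      if (m[r, p] >= 0) {
        res <- max(res, m[r, p] + best(r + 1L, setdiff(free_p, p)))
      }
    }
    res
  }
  best(1L, seq_len(np))
}

# Channels derived consistently from the same gold: span tags from the
# flattened gold, ID tags from `id_source` (gold or a model), dictionary
# features/matches from the lexicon.
gold_channels <- function(entry, lexicon, config = strategy_config(),
                          id_tags = NULL) {
  tokens <- tokenize(entry$doc)
  lab <- encode_labels(entry$doc, entry$annotations, config, tokens)
  tagged <- dict_tag(entry$doc, tokens, lexicon)
  list(tokens = labelled_tokens(tokens, span_tag = lab$span_tag,
                                id_tag = if (is.null(id_tags)) lab$id_tag else id_tags,
                                dict = tagged$features),
       matches = tagged$matches,
       flat = flatten_annotations(entry$annotations, config, tokens))
}

# Flattened gold as a canonical comparable set of (concept, start, end).
flat_key <- function(flat) {
  sort(sprintf("%s:%d-%d", flat$concept_id, flat$start, flat$end))
}

ann_key <- function(anns) {
  sort(vapply(anns, function(a) {
    paste0(a$concept_id, ":", paste(sprintf("%d-%d", a$spans[, "start"],
                                            a$spans[, "end"]), collapse = ";"))
  }, ""))
}
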