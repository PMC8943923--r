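# Small hand-built harmonisation inputs: a 4-token document with channels
# set per case.
h_input <- function(span_tag, id_tag, dict = NULL) {
  labelled_tokens(tokenize("alpha beta gamma delta"), span_tag, id_tag, dict)
}
h_matches <- function(...) {
  rows <- list(...)
  do.call(rbind, c(list(data.frame(concept_id = character(), start = integer(),
                                   end = integer(), stringsAsFactors = FALSE)),
                   lapply(rows, function(r) {
                     data.frame(concept_id = r[[1]], start = as.integer(r[[2]]),
                                end = as.integer(r[[3]]), stringsAsFactors = FALSE)
                   })))
}

test_that("spans-only takes dictionary IDs and drops unsupported entities", {
  # span entity over tokens 1-2 with an identical dictionary match
  inp <- h_input(c("B", "E", "O", "O"), c("NIL", "NIL", "NIL", "NIL"),
                 dict = list("P:1", "P:1", character(), character()))
  out <- spans_only(inp, h_matches(list("P:1", 0, 10)))
  expect_equal(ann_key(out), "P:1:0-10")
  # two same-span candidates: lexically lowest ID wins
  out <- spans_only(inp, h_matches(list("Z:9", 0, 10), list("A:1", 0, 10)))
  expect_equal(out[[1]]$concept_id, "A:1")
  # better-overlapping candidate beats lexical order
  out <- spans_only(inp, h_matches(list("Z:9", 0, 10), list("A:1", 0, 5)))
  expect_equal(out[[1]]$concept_id, "Z:9")
  # no supporting dictionary match: entity dropped
  expect_length(spans_only(inp, h_matches()), 0)
  # the ID channel is ignored entirely
  inp2 <- h_input(c("B", "E", "O", "O"), c("Q:7", "Q:7", "NIL", "NIL"))
  out <- spans_only(inp2, h_matches(list("P:1", 0, 10)))
  expect_equal(out[[1]]$concept_id, "P:1")
})

test_that("ids-only groups maximal runs of identical IDs, overriding spans", {
  inp <- h_input(c("O", "O", "O", "O"), c("X:1", "X:1", "NIL", "Y:1"))
  out <- ids_only(inp)
  expect_equal(ann_key(out), c("X:1:0-10", "Y:1:17-22"))
  # an O span tag cannot veto a non-NIL ID prediction
  one <- h_input(c("O", "O", "O", "O"), c("X:1", "NIL", "NIL", "NIL"))
  expect_equal(ann_key(ids_only(one)), "X:1:0-5")
  none <- h_input(rep("O", 4), rep("NIL", 4))
  expect_length(ids_only(none), 0)
  # adjacent runs of different IDs stay separate
  two <- h_input(c("O", "O", "O", "O"), c("X:1", "X:1", "Y:1", "Y:1"))
  expect_equal(ann_key(ids_only(two)), c("X:1:0-10", "Y:1:11-22"))
})

test_that("spans-first backs off to ID predictions on unclaimed tokens", {
  # span channel silent, ID channel confident: backoff emits the ID entity
  inp <- h_input(c("O", "O", "O", "O"), c("X:1", "NIL", "NIL", "NIL"))
  expect_length(spans_only(inp, h_matches()), 0)
  out <- harmonise(inp, h_matches(), "spans-first")
  expect_equal(ann_key(out), "X:1:0-5")
  # ID run truncated to the sub-run not claimed by a span entity
  inp2 <- h_input(c("B", "E", "O", "O"), c("Y:2", "Y:2", "Y:2", "NIL"),
                  dict = list("P:1", "P:1", character(), character()))
  out2 <- harmonise(inp2, h_matches(list("P:1", 0, 10)), "spans-first")
  expect_equal(ann_key(out2), c("P:1:0-10", "Y:2:11-16"))
  # all channels empty -> nothing, under every strategy
  empty <- h_input(rep("O", 4), rep("NIL", 4))
  for (s in c("spans-only", "ids-only", "spans-first", "ids-first")) {
    expect_length(harmonise(empty, h_matches(), s), 0)
  }
})

test_that("ids-first claims first and re-validates span remnants against the dictionary", {
  # span entity on tokens 1-2 (dict D:1), ID entity on tokens 2-3:
  # the ID entity wins its tokens; the span remnant (token 1) survives only
  # with dictionary support
  inp <- h_input(c("B", "E", "O", "O"), c("NIL", "X:5", "X:5", "NIL"),
                 dict = list("D:1", "D:1", character(), character()))
  out <- harmonise(inp, h_matches(list("D:1", 0, 10)), "ids-first")
  expect_equal(ann_key(out), c("D:1:0-5", "X:5:6-16"))
  # same but without any dictionary match overlapping the remnant
  out2 <- harmonise(inp, h_matches(list("D:1", 6, 10)), "ids-first")
  expect_equal(ann_key(out2), "X:5:6-16")
  expect_error(harmonise(inp, h_matches(), "middle-out"), "unknown")
})

test_that("the relevance pattern space has exactly eight cells", {
  tags <- expand.grid(span = c("O", "S"), id = c("NIL", "X:1"),
                      dict = c(FALSE, TRUE), stringsAsFactors = FALSE)
  toks <- labelled_tokens(
    tokenize(paste(rep("w", 8), collapse = " ")),
    span_tag = tags$span, id_tag = tags$id,
    dict = lapply(tags$dict, function(d) if (d) "X:1" else character()))
  pats <- relevance_pattern(toks)
  expect_length(unique(pats), 8L)
  two <- labelled_tokens(tokenize("alpha beta"), c("O", "S"), c("NIL", "X:1"),
                         list(character(), "X:1"))
  expect_equal(relevance_pattern(two), c("000", "111"))
})

test_that("strategy outputs are nested: base strategies within their backoffs", {
  ont <- gen_ontology(20, seed = 91)
  lex <- build_lexicon(ont)
  cp <- gen_corpus(ont, corpus_spec(n_docs = 3, sentences_per_doc = 4,
                                    seed = 92))
  for (i in seq_along(cp$train)) {
    e <- cp$train[[i]]
    ch <- gold_channels(e, lex)
    noisy <- corrupt_labels(ch$tokens, 0.3, 0.3, 0.3, seed = 1000 + i)
    noisy$dict <- ch$tokens$dict
    so <- ann_key(harmonise(noisy, ch$matches, "spans-only"))
    sf <- ann_key(harmonise(noisy, ch$matches, "spans-first"))
    io <- ann_key(harmonise(noisy, ch$matches, "ids-only"))
    ifi <- ann_key(harmonise(noisy, ch$matches, "ids-first"))
    expect_true(all(so %in% sf))
    expect_true(all(io %in% ifi))
  }
})

test_that("with agreeing channels every strategy recovers the flattened gold", {
  ont <- gen_ontology(20, seed = 95)
  lex <- build_lexicon(ont)
  cp <- gen_corpus(ont, corpus_spec(n_docs = 3, sentences_per_doc = 4,
                                    p_discontinuous = 0, p_overlap = 0.3,
                                    p_ambiguous_surface = 0, seed = 96))
  for (e in cp$train) {
    ch <- gold_channels(e, lex)
    want <- flat_key(ch$flat)
    for (s in c("spans-only", "ids-only", "spans-first", "ids-first")) {
      got <- harmonise(ch$tokens, ch$matches, s)
      expect_equal(ann_key(got), want, label = s)
    }
  }
})

test_that("harmonised output is non-overlapping and stable under re-encoding", {
  ont <- gen_ontology(20, seed = 97)
  lex <- build_lexicon(ont)
  cp <- gen_corpus(ont, corpus_spec(n_docs = 2, sentences_per_doc = 4,
                                    seed = 98))
  for (i in seq_along(cp$train)) {
    e <- cp$train[[i]]
    ch <- gold_channels(e, lex)
    noisy <- corrupt_labels(ch$tokens, 0.4, 0.4, 0.4, seed = 2000 + i)
    noisy$dict <- ch$tokens$dict
    tok <- tokenize(e$doc)
    for (s in c("spans-only", "ids-only", "spans-first", "ids-first")) {
      out <- harmonise(noisy, ch$matches, s, doc = e$doc)
      if (length(out) > 1) {
        for (a in seq_len(length(out) - 1)) {
          expect_false(spans_overlap(out[[a]]$spans, out[[a + 1]]$spans))
        }
      }
      # encode -> strict decode round-trips the harmonised set
      lab <- encode_labels(e$doc, out, tokens = tok)
      expect_equal(ann_key(decode_entities(lab, repair = FALSE, doc = e$doc)),
                   ann_key(out))
    }
  }
})
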