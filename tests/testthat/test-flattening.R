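test_that("tokenisation yields alnum runs and punctuation singletons", {
  expect_equal(tokenize("Ephrin-B1")$surface, c("Ephrin", "-", "B1"))
  tok <- tokenize("ES and somatic cells")
  expect_equal(tok$surface, c("ES", "and", "somatic", "cells"))
  expect_equal(tok$start, c(0L, 3L, 7L, 15L))
  expect_equal(tok$end, c(2L, 6L, 14L, 20L))
  expect_equal(nrow(tokenize("")), 0L)
  # every non-space character is covered, tokens sorted and disjoint
  s <- "a-b  (c3) x"
  tok <- tokenize(s)
  expect_equal(sum(tok$end - tok$start), nchar(gsub("\\s", "", s)))
  expect_true(all(diff(tok$start) > 0))
})

test_that("unification keeps the chosen fragment(s)", {
  a <- annotation("T1", "X:1", list(c(0, 2), c(15, 20)))
  expect_equal(unify_discontinuous(a, "first-span")[, c("start", "end")],
               data.frame(start = 0L, end = 2L))
  expect_equal(unify_discontinuous(a, "last-span")[, c("start", "end")],
               data.frame(start = 15L, end = 20L))
  expect_equal(unify_discontinuous(a, "full-span")[, c("start", "end")],
               data.frame(start = 0L, end = 20L))
  b <- annotation("T2", "X:1", c(7, 20))
  for (s in c("first-span", "full-span", "last-span")) {
    expect_equal(unify_discontinuous(b, s)[, c("start", "end")],
                 data.frame(start = 7L, end = 20L))
  }
})

test_that("unnesting greedily resolves overlaps by length preference", {
  flat <- data.frame(concept_id = c("A:1", "B:1"), start = c(0L, 7L),
                     end = c(20L, 20L), stringsAsFactors = FALSE)
  expect_equal(unnest_overlaps(flat, "keep-longer")$concept_id, "A:1")
  expect_equal(unnest_overlaps(flat, "keep-shorter")$concept_id, "B:1")
  disjoint <- data.frame(concept_id = c("A:1", "B:1"), start = c(0L, 7L),
                         end = c(2L, 20L), stringsAsFactors = FALSE)
  for (s in c("keep-longer", "keep-shorter")) {
    expect_equal(nrow(unnest_overlaps(disjoint, s)), 2L)
  }
  # equal lengths: start, then lexically lowest concept ID break the tie
  tie <- data.frame(concept_id = c("Z:9", "A:1"), start = c(0L, 0L),
                    end = c(5L, 5L), stringsAsFactors = FALSE)
  expect_equal(unnest_overlaps(tie, "keep-longer")$concept_id, "A:1")
})

test_that("sub-word spans snap to whole-token boundaries, idempotently", {
  tok <- tokenize("hexokinase")
  f <- data.frame(concept_id = "P:1", start = 0L, end = 4L)
  snapped <- snap_to_token_boundaries(f, tok)
  expect_equal(c(snapped$start, snapped$end), c(0L, 10L))
  expect_equal(snap_to_token_boundaries(snapped, tok), snapped)
  tok2 <- tokenize("ab cde")
  f2 <- data.frame(concept_id = "P:1", start = 1L, end = 4L)
  s2 <- snap_to_token_boundaries(f2, tok2)
  expect_equal(c(s2$start, s2$end), c(0L, 6L))
  ws <- data.frame(concept_id = "P:1", start = 2L, end = 3L)
  expect_error(snap_to_token_boundaries(ws, tok2), "no token")
})

test_that("IOBES encoding tags single tokens S and multi-token runs B..E", {
  d <- document("d", "alpha beta gamma delta")
  one <- list(annotation("T1", "X:1", c(6, 10)))
  lab <- encode_labels(d, one)
  expect_equal(lab$span_tag, c("O", "S", "O", "O"))
  expect_equal(lab$id_tag, c("NIL", "X:1", "NIL", "NIL"))
  three <- list(annotation("T1", "X:1", c(6, 22)))
  lab <- encode_labels(d, three)
  expect_equal(lab$span_tag, c("O", "B", "I", "E"))
  lab <- encode_labels(d, list())
  expect_true(all(lab$span_tag == "O") && all(lab$id_tag == "NIL"))
})

test_that("strict decoding inverts encoding and rejects ill-formed input", {
  d <- document("d", "alpha beta gamma delta")
  tok <- tokenize(d)
  lab <- labelled_tokens(tok, span_tag = c("S", "O", "B", "E"),
                         id_tag = c("X:1", "NIL", "Y:1", "Y:1"))
  anns <- decode_entities(lab, repair = FALSE, doc = d)
  expect_equal(ann_key(anns), c("X:1:0-5", "Y:1:11-22"))

  bad_id <- labelled_tokens(tok, span_tag = c("B", "E", "O", "O"),
                            id_tag = c("X:1", "Y:1", "NIL", "NIL"))
  expect_error(decode_entities(bad_id, repair = FALSE), "token 2")
  bad_o <- labelled_tokens(tok, span_tag = c("O", "O", "O", "O"),
                           id_tag = c("X:1", "NIL", "NIL", "NIL"))
  expect_error(decode_entities(bad_o, repair = FALSE), "token 1")
  # repair rule: an ID change splits the entity at the change point
  split <- decode_entities(bad_id, repair = TRUE)
  expect_equal(ann_key(split), c("X:1:0-5", "Y:1:6-10"))
  # repair rules: stray I/E open an entity; B before O closes as single
  stray <- labelled_tokens(tok, span_tag = c("I", "E", "B", "O"),
                           id_tag = c("X:1", "X:1", "Y:1", "NIL"))
  expect_equal(ann_key(decode_entities(stray, repair = TRUE)),
               c("X:1:0-10", "Y:1:11-16"))
})

test_that("encoded labels are always strictly decodable", {
  ont <- gen_ontology(18, seed = 21)
  cp <- gen_corpus(ont, corpus_spec(n_docs = 3, sentences_per_doc = 4,
                                    p_discontinuous = 0.3, p_overlap = 0.3,
                                    seed = 22))
  for (e in c(cp$train, cp$test)) {
    for (u in c("first-span", "full-span", "last-span")) {
      for (n in c("keep-longer", "keep-shorter")) {
        lab <- encode_labels(e$doc, e$annotations, strategy_config(u, n))
        expect_no_error(decode_entities(lab, repair = FALSE))
      }
    }
  }
})

test_that("flattening never increases the annotation count", {
  ont <- gen_ontology(18, seed = 31)
  cp <- gen_corpus(ont, corpus_spec(n_docs = 2, sentences_per_doc = 4,
                                    p_discontinuous = 0.4, p_overlap = 0.4,
                                    seed = 32))
  for (e in cp$train) {
    tok <- tokenize(e$doc)
    for (u in c("first-span", "full-span", "last-span")) {
      for (n in c("keep-longer", "keep-shorter")) {
        flat <- flatten_annotations(e$annotations, strategy_config(u, n), tok)
        expect_lte(nrow(flat), length(e$annotations))
      }
    }
  }
})

test_that("the coordination example yields four flattening outcomes", {
  fx <- coordination_example()
  tok <- tokenize(fx$doc)
  outcomes <- character()
  for (u in c("first-span", "full-span", "last-span")) {
    for (n in c("keep-longer", "keep-shorter")) {
      flat <- flatten_annotations(fx$annotations, strategy_config(u, n), tok)
      outcomes[paste(u, n)] <- paste(flat_key(flat), collapse = "|")
    }
  }
  expect_length(unique(outcomes), 4L)
  # no overlap remains after first-span unification, so unnesting is moot
  expect_identical(outcomes[["first-span keep-longer"]],
                   outcomes[["first-span keep-shorter"]])
  # three of the four outcomes lost one of the two annotations
  expect_equal(sum(!grepl("[|]", unique(outcomes))), 3L)
})
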