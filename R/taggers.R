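# The three prediction channels at desk scale: a dictionary-based ontology
# term tagger, a memorisation tagger standing in for trained sequence
# classifiers (it reproduces their structural constraint of only ever
# predicting labels seen in training), and a seeded corruption oracle used
# to generate controlled channel disagreement.

#' Normalise a term or surface string
#'
#' Lower-cases, replaces punctuation with spaces and collapses whitespace.
#' This is the matching key used by both the dictionary and the
#' memorisation tagger; it is the package's (exact-match) stand-in for
#' fuzzy dictionary lookup.
#'
#' @param term Character vector.
#' @return Normalised character vector.
#' @export
#' @examples
#' normalise_term("X-Gal")  # "x gal"
normalise_term <- function(term) {
  out <- tolower(term)
  out <- gsub("[^\\p{L}\\p{N}]+", " ", out, perl = TRUE)
  trimws(out)
}

#' Build a term lexicon from an ontology
#'
#' Indexes every concept name and synonym (plus caller-supplied extra
#' synonyms) under its normalised form.  Ambiguous surfaces map to several
#' concept IDs.
#'
#' @param ont A [ontology()].
#' @param extra_synonyms Optional named character vector or list mapping
#'   additional term strings to concept IDs (term -> ID).
#' @return An object of class `cr_lexicon`: `terms` (normalised term ->
#'   character vector of IDs) and `max_term_tokens`.
#' @export
build_lexicon <- function(ont, extra_synonyms = NULL) {
  terms <- new.env(parent = emptyenv())
  max_tok <- 0L
  add <- function(raw, id) {
    key <- normalise_term(raw)
    if (!nzchar(key)) return()
    ids <- if (!is.null(terms[[key]])) terms[[key]] else character()
    terms[[key]] <- sort(unique(c(ids, id)))
    max_tok <<- max(max_tok, nrow(tokenize(raw)))
  }
  for (id in ont$ids) {
    for (syn in ont$synonyms[[id]]) add(syn, id)
  }
  if (!is.null(extra_synonyms)) {
    for (i in seq_along(extra_synonyms)) {
      id <- extra_synonyms[[i]]
      if (!id %in% ont$ids) {
        stop(sprintf("extra synonym '%s' refers to unknown concept '%s'",
                     names(extra_synonyms)[[i]], id), call. = FALSE)
      }
      add(names(extra_synonyms)[[i]], id)
    }
  }
  structure(list(terms = as.list(terms), max_term_tokens = max_tok),
            class = "cr_lexicon")
}

#' @export
print.cr_lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %d normalised terms, max %d tokens>\n",
              length(x$terms), x$max_term_tokens))
  invisible(x)
}

#' Dictionary-tag a document
#'
#' Reports every token n-gram (n up to the longest lexicon term) whose
#' normalised surface is in the lexicon.  Overlapping and nested matches
#' are all reported; an ambiguous match is expanded to one flat annotation
#' per candidate ID.  Per-token dictionary features collect the IDs of all
#' matches covering the token.
#'
#' @param doc A [document()].
#' @param tokens Token table from [tokenize()].
#' @param lexicon A [build_lexicon()] result.
#' @return `list(matches, features)`: `matches` is a flat annotation data
#'   frame (one row per match x candidate ID), `features` a list of
#'   concept-ID character vectors parallel to `tokens`.
#' @export
dict_tag <- function(doc, tokens, lexicon) {
  n <- nrow(tokens)
  features <- rep(list(character()), n)
  matches <- list()
  for (i in seq_len(if (lexicon$max_term_tokens > 0L) n else 0L)) {
    for (j in i:min(n, i + lexicon$max_term_tokens - 1L)) {
      surface <- substring(doc$text, tokens$start[i] + 1L, tokens$end[j])
      ids <- lexicon$terms[[normalise_term(surface)]]
      if (is.null(ids)) next
      matches[[length(matches) + 1L]] <-
        flat_frame(ids, rep(tokens$start[i], length(ids)),
                   rep(tokens$end[j], length(ids)))
      for (t in i:j) features[[t]] <- sort(unique(c(features[[t]], ids)))
    }
  }
  matches <- do.call(rbind, c(list(flat_frame()), matches))
  rownames(matches) <- NULL
  list(matches = matches, features = features)
}

#' Train a memorisation tagger
#'
#' Counts the normalised surface of every flattened gold annotation against
#' its concept ID.  The resulting model can only ever predict concept IDs
#' present in its training data (`label_set`) — the structural constraint of
#' example-based sequence taggers.
#'
#' @param corpus List of `list(doc, annotations)` entries.
#' @param channel `"span"` or `"id"` (recorded for provenance; the model
#'   data are identical).
#' @param config [strategy_config()] used to flatten the gold annotations.
#' @return An object of class `cr_memo`: `surfaces` (normalised surface ->
#'   named count vector over IDs), `label_set`, `max_tokens`, `channel`.
#' @export
train_memorisation <- function(corpus, channel = c("span", "id"),
                               config = strategy_config()) {
  channel <- match.arg(channel)
  surfaces <- new.env(parent = emptyenv())
  max_tok <- 0L
  for (entry in corpus) {
    tokens <- tokenize(entry$doc)
    flat <- flatten_annotations(entry$annotations, config, tokens)
    for (i in seq_len(nrow(flat))) {
      raw <- substring(entry$doc$text, flat$start[i] + 1L, flat$end[i])
      key <- normalise_term(raw)
      if (!nzchar(key)) next
      tab <- if (!is.null(surfaces[[key]])) surfaces[[key]] else integer()
      id <- flat$concept_id[i]
      tab[id] <- if (id %in% names(tab)) tab[[id]] + 1L else 1L
      surfaces[[key]] <- tab
      max_tok <- max(max_tok, nrow(tokenize(raw)))
    }
  }
  surfaces <- as.list(surfaces)
  structure(list(surfaces = surfaces,
                 label_set = sort(unique(unlist(lapply(surfaces, names)))),
                 max_tokens = max_tok, channel = channel),
            class = "cr_memo")
}

#' @export
print.cr_memo <- function(x, ...) {
  cat(sprintf("<memorisation tagger (%s channel): %d surfaces, %d concept IDs>\n",
              x$channel, length(x$surfaces), length(x$label_set)))
  invisible(x)
}

#' Predict with a memorisation tagger
#'
#' Greedy longest-match left-to-right over normalised token n-grams against
#' the memorised surfaces.  A matched n-gram emits IOBES tags and the
#' surface's most frequent concept ID (ties broken by the lexically lowest
#' ID); unmatched tokens are `O`/`NIL`.  Dictionary features are left
#' empty.
#'
#' @param model A [train_memorisation()] result.
#' @param doc A [document()].
#' @param tokens Token table from [tokenize()].
#' @return A labelled-token data frame.
#' @export
predict_memorisation <- function(model, doc, tokens) {
  n <- nrow(tokens)
  span_tag <- rep("O", n)
  id_tag <- rep("NIL", n)
  i <- 1L
  while (i <= n && model$max_tokens > 0L) {
    hit_len <- 0L
    hit_id <- NULL
    for (j in seq(min(n, i + model$max_tokens - 1L), i)) {
      surface <- substring(doc$text, tokens$start[i] + 1L, tokens$end[j])
      tab <- model$surfaces[[normalise_term(surface)]]
      if (is.null(tab)) next
      cand <- names(tab)[tab == max(tab)]
      hit_id <- sort(cand)[[1L]]
      hit_len <- j - i + 1L
      break
    }
    if (hit_len == 0L) {
      i <- i + 1L
      next
    }
    idx <- i:(i + hit_len - 1L)
    span_tag[idx] <- if (hit_len == 1L) "S" else {
      c("B", rep("I", hit_len - 2L), "E")
    }
    id_tag[idx] <- hit_id
    i <- i + hit_len
  }
  labelled_tokens(tokens, span_tag = span_tag, id_tag = id_tag)
}

# Run expr with a private, restored RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Entity-level corruption of one channel: returns the (possibly shifted /
# relabelled / dropped) entity runs as token-index ranges.
corrupt_entity_runs <- function(runs, n_tokens, p_span_flip, p_id_swap,
                                p_drop, label_set) {
  keep <- logical(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    if (stats::runif(1) < p_drop) next
    keep[k] <- TRUE
    if (stats::runif(1) < p_id_swap && length(setdiff(label_set, runs$id[k]))) {
      pool <- setdiff(label_set, runs$id[k])
      runs$id[k] <- pool[[sample.int(length(pool), 1L)]]
    }
    if (stats::runif(1) < p_span_flip) {
      # move one boundary by one token where the document allows it
      others <- setdiff(which(keep), k)
      grow_first <- runs$first[k] > 1L &&
        !any(runs$last[others] == runs$first[k] - 1L)
      shrink_last <- runs$last[k] > runs$first[k]
      grow_last <- runs$last[k] < n_tokens
      moves <- c(if (grow_first) "grow_first", if (shrink_last) "shrink_last",
                 if (grow_last) "grow_last")
      if (length(moves)) {
        mv <- moves[[sample.int(length(moves), 1L)]]
        if (mv == "grow_first") runs$first[k] <- runs$first[k] - 1L
        if (mv == "shrink_last") runs$last[k] <- runs$last[k] - 1L
        if (mv == "grow_last") runs$last[k] <- runs$last[k] + 1L
      }
    }
  }
  runs <- runs[keep, , drop = FALSE]
  # shifting can create overlaps between neighbouring entities; resolve by
  # keeping the earlier entity and trimming the later one
  if (nrow(runs) > 1L) {
    runs <- runs[order(runs$first, runs$last), , drop = FALSE]
    drop <- logical(nrow(runs))
    for (k in 2L:nrow(runs)) {
      if (runs$first[k] <= runs$last[k - 1L]) {
        runs$first[k] <- runs$last[k - 1L] + 1L
        if (runs$first[k] > runs$last[k]) drop[k] <- TRUE
      }
    }
    runs <- runs[!drop, , drop = FALSE]
  }
  runs
}

runs_to_channels <- function(runs, n_tokens) {
  span_tag <- rep("O", n_tokens)
  id_tag <- rep("NIL", n_tokens)
  for (k in seq_len(nrow(runs))) {
    idx <- runs$first[k]:runs$last[k]
    span_tag[idx] <- if (length(idx) == 1L) "S" else {
      c("B", rep("I", length(idx) - 2L), "E")
    }
    id_tag[idx] <- runs$id[k]
  }
  list(span_tag = span_tag, id_tag = id_tag)
}

#' Seeded corruption of gold token labels
#'
#' Produces controlled disagreement between the span and ID channels for
#' harmonisation experiments.  Each channel is corrupted independently at
#' the entity level: with `p_drop` an entity disappears from the channel
#' (its tokens become `O`/`NIL`); with `p_id_swap` its concept ID is
#' replaced by a different ID drawn uniformly from `label_set`; with
#' `p_span_flip` one entity boundary moves by one token where possible.
#' Deterministic given `(input, seed)`.
#'
#' @param labelled Well-formed labelled tokens (e.g. from
#'   [encode_labels()]).
#' @param p_span_flip,p_id_swap,p_drop Probabilities in `[0, 1]`.
#' @param seed Integer seed (mandatory).
#' @param label_set ID pool for swaps; defaults to the IDs present in
#'   `labelled`.
#' @return A labelled-token data frame whose span channel and ID channel
#'   come from two independent corruption passes.
#' @export
corrupt_labels <- function(labelled, p_span_flip = 0, p_id_swap = 0,
                           p_drop = 0, seed, label_set = NULL) {
  stopifnot(p_span_flip >= 0, p_span_flip <= 1, p_id_swap >= 0,
            p_id_swap <= 1, p_drop >= 0, p_drop <= 1)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  gold <- decode_runs(labelled$span_tag, labelled$id_tag, repair = FALSE)
  if (is.null(label_set)) label_set <- unique(gold$id)
  n <- nrow(labelled)
  with_seed(seed, {
    span_runs <- corrupt_entity_runs(gold, n, p_span_flip, p_id_swap, p_drop,
                                     label_set)
    id_runs <- corrupt_entity_runs(gold, n, p_span_flip, p_id_swap, p_drop,
                                   label_set)
    labelled_tokens(labelled,
                    span_tag = runs_to_channels(span_runs, n)$span_tag,
                    id_tag = runs_to_channels(id_runs, n)$id_tag,
                    dict = labelled$dict)
  })
}
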