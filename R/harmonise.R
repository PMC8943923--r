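# Harmonisation of the three parallel prediction channels (IOBES span tags,
# concept-ID tags, dictionary matches) into one final annotation set.
#
# Four rule-based strategies with a predetermined bias: spans-only,
# ids-only, and their backoff combinations spans-first and ids-first.
# Score-based mixing strategies are deliberately not implemented.

HARMONISATION_STRATEGIES <- c("spans-only", "ids-only", "spans-first",
                              "ids-first")

char_span_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0L, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  if (union == 0L) 0 else inter / union
}

# Pick a concept ID for an entity char span from the dictionary matches
# overlapping it: rank by character Jaccard (descending), break ties by the
# lexically lowest ID.  NULL when no match overlaps.
pick_dict_id <- function(start, end, dict_matches) {
  if (is.null(dict_matches) || nrow(dict_matches) == 0L) return(NULL)
  hit <- which(dict_matches$start < end & dict_matches$end > start)
  if (!length(hit)) return(NULL)
  j <- vapply(hit, function(k) {
    char_span_jaccard(start, end, dict_matches$start[k], dict_matches$end[k])
  }, 0)
  cand <- dict_matches[hit, , drop = FALSE]
  cand <- cand[order(-j, cand$concept_id), , drop = FALSE]
  cand$concept_id[[1L]]
}

# Internal representation of harmonised entities: token-index runs with an
# ID.  Converted to annotations only at the end.
runs_frame <- function(first = integer(), last = integer(), id = character()) {
  data.frame(first = as.integer(first), last = as.integer(last),
             id = as.character(id), stringsAsFactors = FALSE)
}

spans_only_runs <- function(tokens, dict_matches) {
  runs <- decode_runs(tokens$span_tag, id_tag = NULL, repair = TRUE)
  out <- runs_frame()
  for (k in seq_len(nrow(runs))) {
    id <- pick_dict_id(tokens$start[runs$first[k]], tokens$end[runs$last[k]],
                       dict_matches)
    if (is.null(id)) next # span prediction without a supporting feature
    out <- rbind(out, runs_frame(runs$first[k], runs$last[k], id))
  }
  out
}

ids_only_runs <- function(tokens) {
  # maximal runs of identical non-NIL IDs; span channel and dictionary are
  # ignored, so an O span tag cannot veto an ID prediction
  id <- tokens$id_tag
  n <- length(id)
  out <- runs_frame()
  i <- 1L
  while (i <= n) {
    if (id[[i]] == "NIL") {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && id[[j + 1L]] == id[[i]]) j <- j + 1L
    out <- rbind(out, runs_frame(i, j, id[[i]]))
    i <- j + 1L
  }
  out
}

# Truncate `runs` to their maximal contiguous token sub-runs not claimed by
# `claimed` (a logical vector over tokens); empty remnants vanish.
truncate_runs <- function(runs, claimed) {
  out <- runs_frame()
  for (k in seq_len(nrow(runs))) {
    idx <- runs$first[k]:runs$last[k]
    free <- idx[!claimed[idx]]
    if (!length(free)) next
    brk <- c(0L, which(diff(free) > 1L), length(free))
    for (b in seq_len(length(brk) - 1L)) {
      piece <- free[(brk[b] + 1L):brk[b + 1L]]
      out <- rbind(out, runs_frame(piece[[1L]], piece[[length(piece)]],
                                   runs$id[k]))
    }
  }
  out
}

claim <- function(runs, n) {
  claimed <- logical(n)
  for (k in seq_len(nrow(runs))) claimed[runs$first[k]:runs$last[k]] <- TRUE
  claimed
}

runs_to_annotations <- function(runs, tokens, doc = NULL) {
  runs <- runs[order(runs$first, runs$last, runs$id), , drop = FALSE]
  lapply(seq_len(nrow(runs)), function(k) {
    i <- runs$first[k]; j <- runs$last[k]
    txt <- if (is.null(doc)) {
      paste(tokens$surface[i:j], collapse = " ")
    } else {
      substring(doc$text, tokens$start[i] + 1L, tokens$end[j])
    }
    annotation(sprintf("T%d", k), runs$id[k],
               c(tokens$start[i], tokens$end[j]), text = txt)
  })
}

#' Relevance pattern of a token
#'
#' Each channel either flags the token as relevant or not: span tag
#' different from `O`, ID tag different from `NIL`, non-empty dictionary
#' feature set.  The three binary decisions give 2 x 2 x 2 = 8 possible
#' patterns, the case space every harmonisation strategy must cover.
#'
#' @param labelled A labelled-token data frame.
#' @return Character vector of patterns like `"101"` (span, id, dict).
#' @export
relevance_pattern <- function(labelled) {
  paste0(as.integer(labelled$span_tag != "O"),
         as.integer(labelled$id_tag != "NIL"),
         as.integer(lengths(labelled$dict) > 0L))
}

#' Harmonise parallel prediction channels
#'
#' Merges the span-tag, concept-ID and dictionary channels into one final,
#' pairwise non-overlapping annotation set.
#'
#' * `spans-only`: IOBES entities are decoded (with repair) from the span
#'   channel; each entity takes the ID of its best-overlapping dictionary
#'   match (character Jaccard, ties to the lexically lowest ID); entities
#'   with no supporting dictionary match are dropped.  ID predictions are
#'   ignored.
#' * `ids-only`: maximal runs of identical non-NIL ID predictions become
#'   annotations; span channel and dictionary are ignored.
#' * `spans-first`: `spans-only` first; `ids-only` entities are then
#'   truncated to the token runs not claimed by the former and appended
#'   (the backoff for O-NIL outcomes).
#' * `ids-first`: symmetric; truncated span-channel remnants must again
#'   find an overlapping dictionary match (a concept label is always
#'   required), with the ID re-selected on the remnant span.
#'
#' @param tokens Labelled-token data frame with all three channels.
#' @param dict_matches Flat annotation data frame of entity-level
#'   dictionary matches (e.g. `dict_tag(...)$matches`); may be empty.
#' @param strategy One of `"spans-only"`, `"ids-only"`, `"spans-first"`,
#'   `"ids-first"`.
#' @param doc Optional [document()] for exact annotation texts.
#' @return List of contiguous, pairwise non-overlapping [annotation()]
#'   objects, sorted by position.
#' @export
harmonise <- function(tokens, dict_matches = NULL,
                      strategy = HARMONISATION_STRATEGIES, doc = NULL) {
  if (length(strategy) != 1L || !strategy %in% HARMONISATION_STRATEGIES) {
    strategy <- tryCatch(match.arg(strategy, HARMONISATION_STRATEGIES),
                         error = function(e) {
                           stop(sprintf("unknown harmonisation strategy '%s'",
                                        paste(strategy, collapse = ",")),
                                call. = FALSE)
                         })
  }
  n <- nrow(tokens)
  runs <- switch(strategy,
    "spans-only" = spans_only_runs(tokens, dict_matches),
    "ids-only" = ids_only_runs(tokens),
    "spans-first" = {
      e1 <- spans_only_runs(tokens, dict_matches)
      rest <- truncate_runs(ids_only_runs(tokens), claim(e1, n))
      rbind(e1, rest)
    },
    "ids-first" = {
      e1 <- ids_only_runs(tokens)
      rest <- truncate_runs(spans_only_runs(tokens, dict_matches),
                            claim(e1, n))
      ok <- runs_frame()
      for (k in seq_len(nrow(rest))) {
        id <- pick_dict_id(tokens$start[rest$first[k]],
                           tokens$end[rest$last[k]], dict_matches)
        if (is.null(id)) next
        ok <- rbind(ok, runs_frame(rest$first[k], rest$last[k], id))
      }
      rbind(e1, ok)
    })
  runs_to_annotations(runs, tokens, doc)
}

#' @rdname harmonise
#' @export
spans_only <- function(tokens, dict_matches, doc = NULL) {
  harmonise(tokens, dict_matches, "spans-only", doc)
}

#' @rdname harmonise
#' @export
ids_only <- function(tokens, doc = NULL) {
  harmonise(tokens, NULL, "ids-only", doc)
}
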