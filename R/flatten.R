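# Lossy conversion between standoff annotations and token-level label
# sequences: tokenisation, unification of discontinuous mentions, unnesting
# of overlaps, sub-word extension, IOBES/ID encoding and decoding.

SPAN_TAGS <- c("B", "I", "O", "E", "S")

#' Tokenise a document
#'
#' Tokens are maximal runs of Unicode letters and digits, or single
#' non-space punctuation characters.  Every non-space character belongs to
#' exactly one token.  The rule is deterministic and language-independent.
#'
#' @param doc A [document()] or a plain string.
#' @return A data frame with columns `surface`, `start`, `end` (0-based,
#'   half-open), sorted by `start`.
#' @export
#' @examples
#' tokenize("Ephrin-B1")$surface  # "Ephrin" "-" "B1"
tokenize <- function(doc) {
  text <- if (inherits(doc, "cr_document")) doc$text else doc
  empty <- data.frame(surface = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(surface = substring(text, start + 1L, end),
             start = start, end = end, stringsAsFactors = FALSE)
}

# A "flat" annotation set is a data frame with columns concept_id, start,
# end (one contiguous span per row).
flat_frame <- function(concept_id = character(), start = integer(),
                       end = integer()) {
  data.frame(concept_id = as.character(concept_id),
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Unify a discontinuous annotation to one contiguous span
#'
#' `first-span` keeps only the first fragment, `last-span` only the last,
#' and `full-span` stretches from the first fragment's start to the last
#' fragment's end.  Contiguous annotations pass through unchanged under
#' every strategy.
#'
#' @param ann A [annotation()].
#' @param strategy `"first-span"`, `"full-span"` or `"last-span"`.
#' @return A one-row flat annotation data frame (`concept_id`, `start`,
#'   `end`).
#' @export
unify_discontinuous <- function(ann, strategy = c("first-span", "full-span",
                                                  "last-span")) {
  strategy <- match.arg(strategy)
  spans <- ann$spans
  k <- nrow(spans)
  span <- switch(strategy,
    "first-span" = spans[1L, ],
    "last-span"  = spans[k, ],
    "full-span"  = c(start = unname(spans[1L, "start"]),
                     end = unname(spans[k, "end"])))
  flat_frame(ann$concept_id, span[["start"]], span[["end"]])
}

#' Remove overlaps among contiguous annotations
#'
#' Candidates are sorted by length (descending for `keep-longer`, ascending
#' for `keep-shorter`), then start, then concept ID, and greedily accepted
#' whenever they overlap no already-accepted annotation.  With more than two
#' mutually overlapping annotations this greedy order generalises the
#' pairwise preference deterministically.
#'
#' @param flat A flat annotation data frame.
#' @param strategy `"keep-longer"` or `"keep-shorter"`.
#' @return A flat annotation data frame, pairwise non-overlapping, sorted by
#'   start.
#' @export
unnest_overlaps <- function(flat, strategy = c("keep-longer", "keep-shorter")) {
  strategy <- match.arg(strategy)
  if (nrow(flat) == 0L) return(flat)
  len <- flat$end - flat$start
  ord <- order(if (strategy == "keep-longer") -len else len,
               flat$start, flat$concept_id)
  flat <- flat[ord, , drop = FALSE]
  keep <- logical(nrow(flat))
  for (i in seq_len(nrow(flat))) {
    acc <- which(keep)
    clash <- any(pmax(flat$start[i], flat$start[acc]) <
                   pmin(flat$end[i], flat$end[acc]))
    keep[i] <- !clash
  }
  out <- flat[keep, , drop = FALSE]
  out <- out[order(out$start, out$end, out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend a span to whole-token boundaries
#'
#' Sub-word annotations are extended to span entire tokens: the span grows
#' to the smallest token-aligned interval covering every token it overlaps.
#' Idempotent on token-aligned spans.
#'
#' @param flat A flat annotation data frame (any number of rows).
#' @param tokens Token table from [tokenize()].
#' @return The flat data frame with token-aligned `start`/`end`.
#' @export
snap_to_token_boundaries <- function(flat, tokens) {
  if (nrow(flat) == 0L) return(flat)
  for (i in seq_len(nrow(flat))) {
    hit <- which(tokens$start < flat$end[i] & tokens$end > flat$start[i])
    if (!length(hit)) {
      stop(sprintf("span [%d,%d) overlaps no token (whitespace-only span)",
                   flat$start[i], flat$end[i]), call. = FALSE)
    }
    flat$start[i] <- min(tokens$start[hit])
    flat$end[i] <- max(tokens$end[hit])
  }
  flat
}

#' Flatten a standoff annotation set
#'
#' The full simplification pipeline: unify discontinuous mentions, snap to
#' token boundaries, then unnest overlaps.  Unnesting runs last because
#' snapping can create new overlaps.
#'
#' @param anns List of [annotation()] objects.
#' @param config A [strategy_config()].
#' @param tokens Token table from [tokenize()] on the same document.
#' @return A flat annotation data frame, token-aligned and pairwise
#'   non-overlapping.
#' @export
flatten_annotations <- function(anns, config, tokens) {
  flat <- do.call(rbind, c(list(flat_frame()),
                           lapply(anns, unify_discontinuous,
                                  strategy = config$unification)))
  flat <- snap_to_token_boundaries(flat, tokens)
  unnest_overlaps(flat, config$unnesting)
}

#' Encode annotations as IOBES / concept-ID token labels
#'
#' Applies [flatten_annotations()] and then labels each token: a
#' single-token entity is tagged `S`; a multi-token entity `B`, `I`...,
#' `E`; all other tokens `O`.  The ID channel carries the entity's concept
#' ID on its tokens and `NIL` elsewhere.  The dictionary channel is left
#' empty.
#'
#' @param doc A [document()].
#' @param gold List of [annotation()] objects for `doc`.
#' @param config A [strategy_config()].
#' @param tokens Optional pre-computed token table.
#' @return A labelled-token data frame: `surface`, `start`, `end`, `dict`
#'   (list column of concept-ID character vectors), `span_tag`, `id_tag`.
#' @export
encode_labels <- function(doc, gold, config = strategy_config(),
                          tokens = tokenize(doc)) {
  flat <- flatten_annotations(gold, config, tokens)
  n <- nrow(tokens)
  span_tag <- rep("O", n)
  id_tag <- rep("NIL", n)
  for (i in seq_len(nrow(flat))) {
    idx <- which(tokens$start >= flat$start[i] & tokens$end <= flat$end[i])
    if (!length(idx)) next
    if (length(idx) == 1L) {
      span_tag[idx] <- "S"
    } else {
      span_tag[idx] <- c("B", rep("I", length(idx) - 2L), "E")
    }
    id_tag[idx] <- flat$concept_id[i]
  }
  labelled_tokens(tokens, span_tag = span_tag, id_tag = id_tag)
}

#' Build a labelled-token table
#'
#' @param tokens Token table from [tokenize()].
#' @param span_tag Character vector of IOBES tags (default all `"O"`).
#' @param id_tag Character vector of concept IDs / `"NIL"`.
#' @param dict List of character vectors of dictionary-feature concept IDs.
#' @return A labelled-token data frame (see [encode_labels()]).
#' @export
labelled_tokens <- function(tokens, span_tag = NULL, id_tag = NULL,
                            dict = NULL) {
  n <- nrow(tokens)
  if (is.null(span_tag)) span_tag <- rep("O", n)
  if (is.null(id_tag)) id_tag <- rep("NIL", n)
  if (is.null(dict)) dict <- rep(list(character()), n)
  if (!all(span_tag %in% SPAN_TAGS)) {
    stop("span tags must be one of B, I, O, E, S", call. = FALSE)
  }
  out <- tokens[, c("surface", "start", "end")]
  out$dict <- lapply(dict, function(d) sort(unique(as.character(d))))
  out$span_tag <- span_tag
  out$id_tag <- id_tag
  rownames(out) <- NULL
  out
}

# Decode token index runs from a span-tag (and optionally ID-tag) sequence.
# Returns a data frame with first/last token index and the run's ID (NA when
# no ID channel is given or the run's ID is NIL).
#
# Repair rules (repair = TRUE):
#   R1  I or E with no open entity opens one (acts as B).
#   R2  an open entity closes before O (or before/after S).
#   R3  an ID change inside an open entity closes it at the change point.
#   R4  a non-NIL ID on an O token opens/continues an entity only when
#       id_driven = TRUE (harmonisation backoff); plain decoding ignores it.
decode_runs <- function(span_tag, id_tag = NULL, repair = FALSE,
                        id_driven = FALSE) {
  n <- length(span_tag)
  has_id <- !is.null(id_tag)
  if (!repair) {
    check_well_formed(span_tag, id_tag)
  }
  id_of <- function(i) if (has_id) id_tag[[i]] else NA_character_
  runs <- list()
  open <- NULL # list(first, id)
  close_run <- function(last) {
    runs[[length(runs) + 1L]] <<- list(first = open$first, last = last,
                                       id = open$id)
    open <<- NULL
  }
  for (i in seq_len(n)) {
    relevant <- span_tag[[i]] != "O" ||
      (id_driven && has_id && id_tag[[i]] != "NIL")
    if (!relevant) {
      if (!is.null(open)) close_run(i - 1L) # R2
      next
    }
    starts_new <- span_tag[[i]] %in% c("B", "S")
    id_change <- !is.null(open) && has_id && !identical(open$id, id_of(i))
    if (!is.null(open) && (starts_new || id_change)) close_run(i - 1L) # R2/R3
    if (is.null(open)) open <- list(first = i, id = id_of(i)) # R1 implicit
    if (span_tag[[i]] %in% c("S", "E")) close_run(i)
  }
  if (!is.null(open)) close_run(n)
  if (!length(runs)) {
    return(data.frame(first = integer(), last = integer(),
                      id = character(), stringsAsFactors = FALSE))
  }
  data.frame(first = vapply(runs, `[[`, 0L, "first"),
             last = vapply(runs, `[[`, 0L, "last"),
             id = vapply(runs, `[[`, "", "id"),
             stringsAsFactors = FALSE)
}

check_well_formed <- function(span_tag, id_tag = NULL) {
  has_id <- !is.null(id_tag)
  fail <- function(i, why) {
    stop(sprintf("ill-formed label sequence at token %d: %s", i, why),
         call. = FALSE)
  }
  open_at <- NA_integer_
  for (i in seq_along(span_tag)) {
    tag <- span_tag[[i]]
    if (has_id) {
      if (tag == "O" && id_tag[[i]] != "NIL") fail(i, "O token with non-NIL ID")
      if (tag != "O" && id_tag[[i]] == "NIL") fail(i, "entity token with NIL ID")
    }
    if (tag %in% c("I", "E")) {
      if (is.na(open_at)) fail(i, sprintf("%s without preceding B", tag))
      if (has_id && id_tag[[i]] != id_tag[[open_at]]) {
        fail(i, "concept ID changes inside an entity")
      }
    }
    if (tag %in% c("B", "S") && !is.na(open_at)) fail(i, "unclosed entity")
    open_at <- switch(tag, B = if (is.na(open_at)) i else open_at,
                      I = open_at, NA_integer_)
  }
  if (!is.na(open_at)) fail(length(span_tag), "entity left open at end")
  invisible(TRUE)
}

#' Decode token labels back into standoff annotations
#'
#' The inverse of [encode_labels()].  With `repair = FALSE` the input must
#' be well-formed (`S` alone; `B`...`E` with a uniform non-NIL ID; `O`
#' exactly where the ID is `NIL`) and any violation raises an error naming
#' the offending token.  With `repair = TRUE` ill-formed sequences are first
#' normalised: stray `I`/`E` open an entity, entities close before `O`/`S`,
#' and an ID change splits the entity at the change point.
#'
#' @param labelled A labelled-token data frame.
#' @param repair Repair ill-formed sequences instead of erroring?
#' @param doc Optional [document()]; when given, annotation texts are
#'   sliced from it rather than re-joined from token surfaces.
#' @return A list of contiguous [annotation()] objects (tokens whose
#'   repaired run has ID `NIL` are dropped).
#' @export
decode_entities <- function(labelled, repair = FALSE, doc = NULL) {
  runs <- decode_runs(labelled$span_tag, labelled$id_tag, repair = repair)
  runs <- runs[!is.na(runs$id) & runs$id != "NIL", , drop = FALSE]
  lapply(seq_len(nrow(runs)), function(k) {
    i <- runs$first[k]; j <- runs$last[k]
    txt <- if (is.null(doc)) {
      paste(labelled$surface[i:j], collapse = " ")
    } else {
      substring(doc$text, labelled$start[i] + 1L, labelled$end[j])
    }
    annotation(sprintf("T%d", k), runs$id[k],
               c(labelled$start[i], labelled$end[j]), text = txt)
  })
}
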