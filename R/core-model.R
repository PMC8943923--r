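# Core domain types: documents, spans, annotations, tokens, ontologies,
# strategy configurations.  Character offsets are 0-based, half-open
# [start, end), following brat/BioNLP standoff practice.

RESERVED_LABELS <- c("NIL", "O")

#' Create a document
#'
#' A document is a piece of text with a stable identifier.  All character
#' offsets used elsewhere in the package refer to 0-based, half-open
#' positions in `text`.
#'
#' @param doc_id Non-empty string identifying the document.
#' @param text Document text (may be empty only for annotation-free
#'   documents).
#' @return An object of class `cr_document` with fields `doc_id` and `text`.
#' @export
#' @examples
#' document("d1", "ES and somatic cells")
document <- function(doc_id, text) {
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id)) {
    stop("doc_id must be a non-empty string", call. = FALSE)
  }
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("text must be a single string", call. = FALSE)
  }
  structure(list(doc_id = doc_id, text = text), class = "cr_document")
}

#' @export
print.cr_document <- function(x, ...) {
  cat(sprintf("<document %s: %d chars>\n", x$doc_id, nchar(x$text)))
  invisible(x)
}

# Normalise a spans argument (matrix, 2-vector, or list of pairs) into an
# n x 2 integer matrix with columns start, end.
as_span_matrix <- function(spans) {
  if (is.list(spans)) {
    spans <- do.call(rbind, lapply(spans, function(s) as.integer(s[1:2])))
  } else if (is.numeric(spans) && is.null(dim(spans))) {
    if (length(spans) != 2L) stop("a single span must have length 2", call. = FALSE)
    spans <- matrix(as.integer(spans), ncol = 2L)
  } else {
    spans <- matrix(as.integer(spans), ncol = 2L)
  }
  colnames(spans) <- c("start", "end")
  spans
}

validate_spans <- function(spans) {
  if (nrow(spans) < 1L) stop("at least one span is required", call. = FALSE)
  if (anyNA(spans)) stop("span offsets must be integers", call. = FALSE)
  if (any(spans[, "start"] < 0L)) stop("span starts must be >= 0", call. = FALSE)
  if (any(spans[, "start"] >= spans[, "end"])) {
    stop("empty or inverted spans are invalid (need start < end)", call. = FALSE)
  }
  spans
}

# Sort fragments by start and merge overlapping or adjacent ones, so that
# the Annotation invariant (sorted, pairwise non-overlapping, non-adjacent)
# holds by construction.
merge_fragments <- function(spans) {
  spans <- spans[order(spans[, "start"], spans[, "end"]), , drop = FALSE]
  out <- spans[1L, , drop = FALSE]
  if (nrow(spans) > 1L) {
    for (i in 2L:nrow(spans)) {
      k <- nrow(out)
      if (spans[i, "start"] <= out[k, "end"]) {
        out[k, "end"] <- max(out[k, "end"], spans[i, "end"])
      } else {
        out <- rbind(out, spans[i, , drop = FALSE])
      }
    }
  }
  out
}

#' Create a concept annotation
#'
#' An annotation is one concept mention: a concept identifier plus an
#' ordered list of character spans.  Discontinuous mentions carry more than
#' one fragment.  Fragments are sorted on construction; overlapping or
#' adjacent fragments are merged so the stored list is always pairwise
#' non-overlapping and non-adjacent.
#'
#' @param ann_id Annotation identifier (e.g. `"T1"`).
#' @param concept_id Concept identifier, e.g. `"CHEBI:22720"`.  The reserved
#'   labels `"NIL"` and `"O"` are rejected.
#' @param spans An n x 2 matrix, a length-2 vector, or a list of
#'   `(start, end)` pairs; 0-based half-open character offsets.
#' @param text Covered text (fragments joined by a single space).  Computed
#'   from `doc` when omitted.
#' @param doc Optional [document()]; when given, `text` is checked (or
#'   derived) against the document.
#' @return An object of class `cr_annotation`.
#' @export
#' @examples
#' d <- document("d1", "ES and somatic cells")
#' annotation("T1", "CL:0002322", list(c(0, 2), c(15, 20)), doc = d)
annotation <- function(ann_id, concept_id, spans, text = NULL, doc = NULL) {
  if (!is.character(concept_id) || length(concept_id) != 1L || !nzchar(concept_id)) {
    stop("concept_id must be a non-empty string", call. = FALSE)
  }
  if (concept_id %in% RESERVED_LABELS) {
    stop(sprintf("'%s' is a reserved label and cannot be a concept ID", concept_id),
         call. = FALSE)
  }
  spans <- merge_fragments(validate_spans(as_span_matrix(spans)))
  if (!is.null(doc)) {
    derived <- covered_text(doc, structure(list(concept_id = concept_id, spans = spans),
                                           class = "cr_annotation"))
    if (is.null(text)) {
      text <- derived
    } else if (!identical(text, derived)) {
      stop(sprintf("annotation %s: covered text mismatch ('%s' vs document '%s')",
                   ann_id, text, derived), call. = FALSE)
    }
  }
  structure(list(ann_id = as.character(ann_id), concept_id = concept_id,
                 spans = spans, text = text),
            class = "cr_annotation")
}

#' @export
print.cr_annotation <- function(x, ...) {
  frags <- paste(sprintf("%d-%d", x$spans[, "start"], x$spans[, "end"]),
                 collapse = ";")
  cat(sprintf("<annotation %s %s [%s] %s>\n", x$ann_id, x$concept_id, frags,
              if (is.null(x$text)) "" else dQuote(x$text, q = FALSE)))
  invisible(x)
}

#' Covered text of an annotation
#'
#' Slices the document at each fragment and joins the pieces with a single
#' space, the conventional rendering of a discontinuous mention.
#'
#' @param doc A [document()].
#' @param ann A [annotation()] (only its `spans` are used).
#' @return A string.
#' @export
covered_text <- function(doc, ann) {
  n <- nchar(doc$text)
  spans <- ann$spans
  if (any(spans[, "end"] > n)) {
    bad <- spans[which(spans[, "end"] > n)[1L], ]
    stop(sprintf("span [%d,%d) out of bounds for document %s (%d chars)",
                 bad["start"], bad["end"], doc$doc_id, n), call. = FALSE)
  }
  paste(substring(doc$text, spans[, "start"] + 1L, spans[, "end"]),
        collapse = " ")
}

#' Do two fragment lists share any character?
#'
#' @param a,b Span matrices (or anything [annotation()] accepts as spans),
#'   each internally non-overlapping.
#' @return `TRUE` iff some character offset is covered by both lists.
#'   Half-open spans make touching fragments non-overlapping.
#' @export
spans_overlap <- function(a, b) {
  a <- as_span_matrix(a)
  b <- as_span_matrix(b)
  for (i in seq_len(nrow(a))) {
    if (any(pmax(a[i, "start"], b[, "start"]) < pmin(a[i, "end"], b[, "end"]))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Total covered length of an annotation
#'
#' Sum of fragment lengths; the quantity compared by the keep-longer /
#' keep-shorter unnesting strategies.
#'
#' @param ann A [annotation()], or a span matrix.
#' @return Integer number of covered characters.
#' @export
total_length <- function(ann) {
  spans <- if (inherits(ann, "cr_annotation")) ann$spans else as_span_matrix(ann)
  sum(spans[, "end"] - spans[, "start"])
}

#' Strategy configuration
#'
#' The central hyperparameters of the pipeline: how discontinuous
#' annotations are unified to one contiguous span, how overlapping
#' annotations are unnested, and how the parallel prediction channels are
#' harmonised.
#'
#' @param unification `"first-span"`, `"full-span"` or `"last-span"`.
#' @param unnesting `"keep-longer"` or `"keep-shorter"`.
#' @param harmonisation `"spans-only"`, `"ids-only"`, `"spans-first"` or
#'   `"ids-first"`.
#' @return An object of class `cr_strategy`.
#' @export
strategy_config <- function(unification = c("first-span", "full-span", "last-span"),
                            unnesting = c("keep-longer", "keep-shorter"),
                            harmonisation = c("spans-first", "spans-only",
                                              "ids-only", "ids-first")) {
  structure(list(unification = match.arg(unification),
                 unnesting = match.arg(unnesting),
                 harmonisation = match.arg(harmonisation)),
            class = "cr_strategy")
}

#' @export
print.cr_strategy <- function(x, ...) {
  cat(sprintf("<strategy unify=%s unnest=%s harmonise=%s>\n",
              x$unification, x$unnesting, x$harmonisation))
  invisible(x)
}

#' Construct an ontology
#'
#' A concept graph over `is_a` relations: each concept has a primary name, a
#' synonym set (always including the name) and a set of parent concepts.
#' The parent graph must be acyclic and closed (every parent resolves).
#'
#' @param ids Character vector of concept IDs.
#' @param names Character vector of primary names, parallel to `ids`.
#' @param synonyms List of character vectors, parallel to `ids`.
#' @param parents List of character vectors of parent IDs, parallel to `ids`.
#' @return An object of class `cr_ontology`.
#' @export
ontology <- function(ids, names, synonyms = NULL, parents = NULL) {
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate concept IDs", call. = FALSE)
  if (any(ids %in% RESERVED_LABELS)) {
    stop("'NIL' and 'O' are reserved and cannot be concept IDs", call. = FALSE)
  }
  if (length(names) != n) stop("names must parallel ids", call. = FALSE)
  if (is.null(synonyms)) synonyms <- vector("list", n)
  if (is.null(parents)) parents <- rep(list(character()), n)
  synonyms <- lapply(seq_len(n), function(i) {
    sort(unique(c(names[[i]], synonyms[[i]])))
  })
  parents <- lapply(parents, function(p) sort(unique(as.character(p))))
  missing <- setdiff(unlist(parents), ids)
  if (length(missing)) {
    stop(sprintf("is_a references unknown concept(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  names(synonyms) <- ids
  names(parents) <- ids
  ont <- structure(list(ids = as.character(ids),
                        name = stats::setNames(as.character(names), ids),
                        synonyms = synonyms, parents = parents),
                   class = "cr_ontology")
  assert_acyclic(ont)
  ont
}

# Kahn-style topological check of the is_a graph; errors on a cycle.
assert_acyclic <- function(ont) {
  indeg <- lengths(ont$parents)
  names(indeg) <- ont$ids
  children <- split(rep(ont$ids, lengths(ont$parents)), unlist(ont$parents))
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[id]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(ont$ids)) {
    stop("is_a graph contains a cycle", call. = FALSE)
  }
  invisible(ont)
}

#' @export
print.cr_ontology <- function(x, ...) {
  cat(sprintf("<ontology: %d concepts, %d synonym strings>\n",
              length(x$ids), length(unique(unlist(x$synonyms)))))
  invisible(x)
}

#' Self-inclusive ancestor set of a concept
#'
#' All concepts reachable from `id` via `is_a`, including `id` itself; the
#' basis of the hierarchy-aware concept similarity.
#'
#' @param ont A [ontology()].
#' @param id Concept ID present in `ont`.
#' @return Character vector of concept IDs (sorted).
#' @export
ancestors <- function(ont, id) {
  if (!id %in% ont$ids) stop(sprintf("unknown concept '%s'", id), call. = FALSE)
  out <- character()
  frontier <- id
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(unique(unlist(ont$parents[frontier])), out)
  }
  sort(unique(out))
}
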