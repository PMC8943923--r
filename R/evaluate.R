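# Similarity-weighted scoring of concept annotations: fractional matches
# (character-level Jaccard times ontology-hierarchy similarity), precision,
# recall, F-score and slot error rate, plus the unseen-concept protocol.

#' Character-level Jaccard index of two fragment lists
#'
#' @param a,b Span matrices (or anything [annotation()] accepts), each
#'   internally non-overlapping.
#' @return `|covered(a) n covered(b)| / |covered(a) u covered(b)|` in
#'   `[0, 1]`.
#' @export
char_jaccard <- function(a, b) {
  a <- as_span_matrix(a)
  b <- as_span_matrix(b)
  inter <- 0L
  for (i in seq_len(nrow(a))) {
    inter <- inter + sum(pmax(0L, pmin(a[i, "end"], b[, "end"]) -
                                pmax(a[i, "start"], b[, "start"])))
  }
  la <- sum(a[, "end"] - a[, "start"])
  lb <- sum(b[, "end"] - b[, "start"])
  union <- la + lb - inter
  if (union == 0L) 0 else inter / union
}

#' Hierarchy-aware concept similarity
#'
#' 1 for identical IDs; otherwise the Jaccard index of the two concepts'
#' self-inclusive `is_a` ancestor sets.  An ID absent from the ontology
#' scores 0 against any different ID (with a warning, not an error).
#'
#' @param id_a,id_b Concept IDs.
#' @param ont A [ontology()].
#' @return Similarity in `[0, 1]`.
#' @export
concept_similarity <- function(id_a, id_b, ont) {
  if (identical(id_a, id_b)) return(1)
  known <- c(id_a, id_b) %in% ont$ids
  if (!all(known)) {
    warning(sprintf("concept ID(s) not in ontology: %s",
                    paste(c(id_a, id_b)[!known], collapse = ", ")),
            call. = FALSE)
    return(0)
  }
  anc_a <- ancestors(ont, id_a)
  anc_b <- ancestors(ont, id_b)
  length(intersect(anc_a, anc_b)) / length(union(anc_a, anc_b))
}

assert_non_overlapping <- function(anns, side) {
  if (length(anns) < 2L) return(invisible(TRUE))
  for (i in seq_len(length(anns) - 1L)) {
    for (j in (i + 1L):length(anns)) {
      if (spans_overlap(anns[[i]]$spans, anns[[j]]$spans)) {
        stop(sprintf("%s annotations overlap (%s, %s); flatten them first",
                     side, anns[[i]]$ann_id, anns[[j]]$ann_id), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Align predictions to references and count match mass
#'
#' Candidate pairs are all (reference, prediction) pairs with textual
#' overlap (`j > 0`); they are sorted by similarity `m = j * c`
#' (descending), then `j`, then reference start, then prediction start, and
#' accepted greedily while both members are unused.  Each accepted pair
#' contributes `m` to the match count and `1 - m` to the substitution
#' count; unmatched references are deletions, unmatched predictions
#' insertions.
#'
#' @param reference,predictions Lists of [annotation()] objects, each side
#'   pairwise non-overlapping.
#' @param ont A [ontology()] for the concept similarity.
#' @return An object of class `cr_counts`: `M`, `S`, `I`, `D`, `n_ref`,
#'   `n_pred`.
#' @export
align_and_count <- function(reference, predictions, ont) {
  assert_non_overlapping(reference, "reference")
  assert_non_overlapping(predictions, "prediction")
  nr <- length(reference)
  np <- length(predictions)
  pairs <- NULL
  for (r in seq_len(nr)) {
    for (p in seq_len(np)) {
      j <- char_jaccard(reference[[r]]$spans, predictions[[p]]$spans)
      if (j <= 0) next
      cs <- concept_similarity(reference[[r]]$concept_id,
                               predictions[[p]]$concept_id, ont)
      pairs <- rbind(pairs, data.frame(
        r = r, p = p, j = j, m = j * cs,
        rs = reference[[r]]$spans[1L, "start"],
        ps = predictions[[p]]$spans[1L, "start"]))
    }
  }
  M <- 0; S <- 0
  used_r <- logical(nr)
  used_p <- logical(np)
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs$m, -pairs$j, pairs$rs, pairs$ps), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      if (used_r[pairs$r[k]] || used_p[pairs$p[k]]) next
      used_r[pairs$r[k]] <- TRUE
      used_p[pairs$p[k]] <- TRUE
      M <- M + pairs$m[k]
      S <- S + (1 - pairs$m[k])
    }
  }
  structure(list(M = M, S = S, I = sum(!used_p), D = sum(!used_r),
                 n_ref = nr, n_pred = np),
            class = "cr_counts")
}

#' @export
print.cr_counts <- function(x, ...) {
  cat(sprintf("<counts: M=%.4g S=%.4g I=%d D=%d (ref %d, pred %d)>\n",
              x$M, x$S, x$I, x$D, x$n_ref, x$n_pred))
  invisible(x)
}

#' Precision, recall, F-score and slot error rate from counts
#'
#' `P = M / (M + S + I)`, `R = M / (M + S + D)`,
#' `F = 2PR / (P + R)` (0 when both are 0), and
#' `SER = (S + I + D) / (M + S + D)`.  Conventions for empty inputs: with
#' no references and no predictions, P = R = F = 1 and SER = 0 (nothing to
#' get wrong); with an empty reference but predictions present, P = R =
#' F = 0 and SER is undefined and flagged as `NA`.
#'
#' @param counts A `cr_counts` object (or list with `M`, `S`, `I`, `D`).
#' @return An object of class `cr_metrics`: `precision`, `recall`,
#'   `f_score`, `ser` (`NA` when undefined).
#' @export
compute_metrics <- function(counts) {
  M <- counts$M; S <- counts$S; I <- counts$I; D <- counts$D
  if (any(c(M, S, I, D) < 0)) stop("negative counts", call. = FALSE)
  ref_mass <- M + S + D
  pred_mass <- M + S + I
  if (ref_mass == 0 && pred_mass == 0) {
    return(structure(list(precision = 1, recall = 1, f_score = 1, ser = 0),
                     class = "cr_metrics"))
  }
  P <- if (pred_mass > 0) M / pred_mass else 0
  R <- if (ref_mass > 0) M / ref_mass else 0
  f <- if (P + R > 0) 2 * P * R / (P + R) else 0
  ser <- if (ref_mass > 0) (S + I + D) / ref_mass else NA_real_
  structure(list(precision = P, recall = R, f_score = f, ser = ser),
            class = "cr_metrics")
}

#' @export
print.cr_metrics <- function(x, ...) {
  cat(sprintf("P=%.4f R=%.4f F=%.4f SER=%s\n", x$precision, x$recall,
              x$f_score, if (is.na(x$ser)) "undefined" else sprintf("%.4f", x$ser)))
  invisible(x)
}

#' Restrict annotations to unseen concepts
#'
#' Keeps exactly the annotations whose concept ID is absent from the
#' training label set — the filtering step of the unseen-concept
#' evaluation protocol (applied to reference and predictions alike).
#'
#' @param anns List of [annotation()] objects.
#' @param training_ids Character vector of concept IDs used in training.
#' @return The filtered list.
#' @export
filter_unseen <- function(anns, training_ids) {
  Filter(function(a) !a$concept_id %in% training_ids, anns)
}

#' Evaluate predictions against a reference
#'
#' Optionally applies the unseen-concept filter to both sides, then aligns,
#' counts and derives metrics.
#'
#' @param reference,predictions Lists of [annotation()] objects.
#' @param ont A [ontology()].
#' @param unseen_of Optional character vector of training concept IDs; when
#'   given, both sides are filtered to concepts outside this set first.
#' @return `list(metrics, counts)`.
#' @export
evaluate <- function(reference, predictions, ont, unseen_of = NULL) {
  if (!is.null(unseen_of)) {
    reference <- filter_unseen(reference, unseen_of)
    predictions <- filter_unseen(predictions, unseen_of)
  }
  counts <- align_and_count(reference, predictions, ont)
  list(metrics = compute_metrics(counts), counts = counts)
}
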