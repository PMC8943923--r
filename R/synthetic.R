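# Seeded generators for ontologies and annotated corpora, plus the worked
# coordination example.  Everything is a pure function of (parameters,
# seed), so the whole pipeline is testable without external data.

SYLLABLES <- c("ba", "de", "fi", "go", "lu", "mek", "nor", "pra", "sti",
               "vor", "zel", "kan", "thy", "os", "gli", "ren", "du", "pax")
HEAD_WORDS <- c("cell", "kinase", "acid", "tissue", "factor")
FILLER_WORDS <- c("the", "of", "in", "we", "observed", "expression", "with",
                  "during", "analysis", "samples", "increased", "levels",
                  "this", "study", "measured", "results", "show", "reduced")

#' Specification of a synthetic corpus
#'
#' The knobs of the corpus generator: corpus size, how often concept
#' mentions are planted, and how often the structurally hard cases occur
#' (discontinuous coordination mentions, nested overlapping mentions,
#' ambiguous surface forms), plus the share of concepts reserved for the
#' test split only.
#'
#' @param n_docs Documents per split.
#' @param sentences_per_doc Sentences per document.
#' @param mention_rate Expected planted mentions per sentence.
#' @param p_discontinuous Probability that a mention is realised as a
#'   coordination (`"X and Y Z"`) planting a discontinuous annotation.
#' @param p_overlap Probability that a mention co-annotates a nested
#'   shorter term.
#' @param p_ambiguous_surface Probability that a mention prefers an
#'   ambiguous surface form (one shared by several concepts) when one
#'   exists.
#' @param unseen_fraction Share of the used concepts that appear only in
#'   the test gold (in `[0, 1)`).
#' @param seed Mandatory integer seed.
#' @return An object of class `cr_corpus_spec`.
#' @export
corpus_spec <- function(n_docs = 4, sentences_per_doc = 5, mention_rate = 1.2,
                        p_discontinuous = 0.1, p_overlap = 0.15,
                        p_ambiguous_surface = 0.1, unseen_fraction = 0,
                        seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  probs <- c(p_discontinuous, p_overlap, p_ambiguous_surface)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (unseen_fraction < 0 || unseen_fraction >= 1) {
    stop("unseen_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (n_docs < 1 || sentences_per_doc < 1) {
    stop("corpus must have at least one document and sentence", call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 mention_rate = mention_rate,
                 p_discontinuous = p_discontinuous, p_overlap = p_overlap,
                 p_ambiguous_surface = p_ambiguous_surface,
                 unseen_fraction = unseen_fraction,
                 seed = as.integer(seed)),
            class = "cr_corpus_spec")
}

rand_word <- function(used) {
  repeat {
    w <- paste(sample(SYLLABLES, sample(2:3, 1L), replace = TRUE),
               collapse = "")
    if (!w %in% used && !w %in% c(HEAD_WORDS, FILLER_WORDS)) return(w)
  }
}

#' Generate a random ontology
#'
#' A rooted, acyclic `is_a` graph with IDs `SYN:0000001`, `SYN:0000002`,
#' ...  The first few non-root concepts are named after single head words
#' (`"cell"`, `"kinase"`, ...); most later concepts get two-word names
#' `"<modifier> <head>"`, which gives the corpus generator nested terms and
#' head-sharing pairs for coordination mentions.  Synonym strings are
#' unique unless `p_ambiguous` asks for collisions.
#'
#' @param n_concepts Number of concepts (>= 1).
#' @param max_parents Maximum `is_a` parents per non-root concept.
#' @param n_synonyms Extra synonyms per concept (besides the name).
#' @param seed Mandatory integer seed.
#' @param p_ambiguous Probability that an extra synonym reuses another
#'   concept's surface form.
#' @return A [ontology()].
#' @export
gen_ontology <- function(n_concepts, max_parents = 2, n_synonyms = 1, seed,
                         p_ambiguous = 0) {
  if (n_concepts < 1) stop("n_concepts must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  with_seed(seed, {
    ids <- sprintf("SYN:%07d", seq_len(n_concepts))
    nms <- character(n_concepts)
    syns <- vector("list", n_concepts)
    parents <- rep(list(character()), n_concepts)
    used <- character()
    nms[[1L]] <- "entity"
    n_heads <- min(length(HEAD_WORDS), n_concepts - 1L)
    for (i in seq_len(n_concepts)[-1L]) {
      if (i <= 1L + n_heads) {
        nms[[i]] <- HEAD_WORDS[[i - 1L]]
      } else if (stats::runif(1) < 0.75) {
        nms[[i]] <- paste(rand_word(used), sample(HEAD_WORDS, 1L))
      } else {
        nms[[i]] <- rand_word(used)
      }
      used <- c(used, nms[[i]])
      k <- sample.int(min(max_parents, i - 1L), 1L)
      parents[[i]] <- ids[sample.int(i - 1L, k)]
      extra <- character()
      for (s in seq_len(n_synonyms)) {
        if (stats::runif(1) < p_ambiguous && length(used) > 1L) {
          pool <- setdiff(used, c(nms[[i]], extra))
          if (length(pool)) {
            extra <- c(extra, pool[[sample.int(length(pool), 1L)]])
            next
          }
        }
        w <- if (stats::runif(1) < 0.5) {
          paste(rand_word(used), sample(HEAD_WORDS, 1L))
        } else {
          rand_word(used)
        }
        used <- c(used, w)
        extra <- c(extra, w)
      }
      syns[[i]] <- extra
    }
    ontology(ids, nms, synonyms = syns, parents = parents)
  })
}

# Table of usable surfaces: one row per (concept, synonym) with word count,
# head word (last word) and modifier prefix.
surface_table <- function(ont) {
  rows <- list()
  for (id in setdiff(ont$ids, ont$ids[[1L]])) {
    for (syn in ont$synonyms[[id]]) {
      words <- strsplit(syn, " ", fixed = TRUE)[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        concept_id = id, surface = syn, n_words = length(words),
        head = words[[length(words)]],
        modifier = paste(words[-length(words)], collapse = " "),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# One planted mention: a list of words plus annotation blueprints given as
# word-index fragments relative to the mention.
realise_mention <- function(concept, surfaces, allowed, p_disc, p_over,
                            p_ambig) {
  mine <- surfaces[surfaces$concept_id == concept, , drop = FALSE]
  multi <- mine[mine$n_words >= 2L, , drop = FALSE]
  draw <- stats::runif(1)
  if (draw < p_disc && nrow(multi)) {
    # coordination "X and Y Z": partner shares the head word
    for (k in sample.int(nrow(multi))) {
      partners <- surfaces[surfaces$head == multi$head[k] &
                             surfaces$n_words >= 2L &
                             surfaces$concept_id != concept &
                             surfaces$concept_id %in% allowed, , drop = FALSE]
      if (!nrow(partners)) next
      p <- partners[sample.int(nrow(partners), 1L), ]
      x <- strsplit(multi$modifier[k], " ", fixed = TRUE)[[1L]]
      y <- strsplit(p$modifier, " ", fixed = TRUE)[[1L]]
      words <- c(x, "and", y, p$head)
      nx <- length(x); ny <- length(y)
      return(list(words = words, anns = list(
        list(concept_id = concept,
             frags = list(c(1L, nx), c(nx + ny + 2L, nx + ny + 2L))),
        list(concept_id = p$concept_id,
             frags = list(c(nx + 2L, nx + ny + 2L))))))
    }
  }
  if (draw < p_disc + p_over && nrow(multi)) {
    # nested shorter term: the head word is itself a concept
    for (k in sample.int(nrow(multi))) {
      nested <- surfaces[surfaces$surface == multi$head[k] &
                           surfaces$concept_id != concept &
                           surfaces$concept_id %in% allowed, , drop = FALSE]
      if (!nrow(nested)) next
      words <- strsplit(multi$surface[k], " ", fixed = TRUE)[[1L]]
      nw <- length(words)
      return(list(words = words, anns = list(
        list(concept_id = concept, frags = list(c(1L, nw))),
        list(concept_id = nested$concept_id[[1L]],
             frags = list(c(nw, nw))))))
    }
  }
  # plain mention; optionally prefer an ambiguous surface
  pick <- mine
  if (stats::runif(1) < p_ambig) {
    amb <- mine$surface[mine$surface %in%
                          surfaces$surface[surfaces$concept_id != concept]]
    if (length(amb)) pick <- mine[mine$surface %in% amb, , drop = FALSE]
  }
  row <- pick[sample.int(nrow(pick), 1L), ]
  words <- strsplit(row$surface, " ", fixed = TRUE)[[1L]]
  list(words = words,
       anns = list(list(concept_id = concept,
                        frags = list(c(1L, length(words))))))
}

# Assemble documents from per-sentence mention plans.  `plan` is a list of
# documents; each document a list of sentences; each sentence a list of
# realised mentions.
assemble_docs <- function(plan, id_prefix) {
  docs <- list()
  for (d in seq_along(plan)) {
    words <- character()
    offs <- integer() # running start offset of each word
    anns <- list()
    cursor <- 0L
    add_word <- function(w) {
      words[[length(words) + 1L]] <<- w
      offs[[length(offs) + 1L]] <<- cursor
      cursor <<- cursor + nchar(w) + 1L # single space after every word
    }
    for (sent in plan[[d]]) {
      for (f in seq_len(sample(2:3, 1L))) add_word(sample(FILLER_WORDS, 1L))
      for (m in sent) {
        base <- length(words)
        for (w in m$words) add_word(w)
        for (a in m$anns) {
          spans <- lapply(a$frags, function(fr) {
            c(offs[[base + fr[[1L]]]],
              offs[[base + fr[[2L]]]] + nchar(words[[base + fr[[2L]]]]))
          })
          anns[[length(anns) + 1L]] <- list(concept_id = a$concept_id,
                                            spans = spans)
        }
        for (f in seq_len(sample(1:2, 1L))) add_word(sample(FILLER_WORDS, 1L))
      }
      add_word(".")
    }
    text <- paste(words, collapse = " ")
    doc <- document(sprintf("%s%02d", id_prefix, d), text)
    anns <- lapply(seq_along(anns), function(k) {
      annotation(sprintf("T%d", k), anns[[k]]$concept_id, anns[[k]]$spans,
                 doc = doc)
    })
    docs[[d]] <- list(doc = doc, annotations = anns)
  }
  docs
}

# Per-sentence mention slot counts for one split; total bumped to at least
# `minimum` slots.
slot_counts <- function(n_docs, n_sent, rate, minimum = 0L) {
  counts <- matrix(stats::rpois(n_docs * n_sent, rate), nrow = n_docs)
  while (sum(counts) < minimum) {
    i <- sample.int(length(counts), 1L)
    counts[i] <- counts[i] + 1L
  }
  counts
}

plan_split <- function(queue, counts, surfaces, allowed, spec) {
  plan <- list()
  q <- 1L
  for (d in seq_len(nrow(counts))) {
    sentences <- list()
    for (s in seq_len(ncol(counts))) {
      mentions <- list()
      for (k in seq_len(counts[d, s])) {
        if (q > length(queue)) break
        mentions[[length(mentions) + 1L]] <-
          realise_mention(queue[[q]], surfaces, allowed,
                          spec$p_discontinuous, spec$p_overlap,
                          spec$p_ambiguous_surface)
        q <- q + 1L
      }
      sentences[[s]] <- mentions
    }
    plan[[d]] <- sentences
  }
  plan
}

gold_ids <- function(split) {
  sort(unique(unlist(lapply(split, function(e) {
    vapply(e$annotations, `[[`, "", "concept_id")
  }))))
}

#' Generate a synthetic annotated corpus
#'
#' Builds a train and a test split of documents with planted ontology-term
#' mentions: plain mentions, coordination mentions planting a discontinuous
#' annotation that overlaps a contiguous one (`"X and Y Z"` annotated as
#' `X...Z` and `Y Z`), and nested co-annotations.  A controllable share of
#' the used concepts is reserved for the test split, so the unseen-concept
#' protocol can be exercised: with `unseen_fraction = f`, exactly
#' `ceiling(f * n_used)` of the `n_used` concepts appearing in the corpus
#' occur only in the test gold.
#'
#' @param ont A [ontology()] (e.g. from [gen_ontology()]).
#' @param spec A [corpus_spec()].
#' @return A list with `train` and `test` (each a list of
#'   `list(doc, annotations)`), `training_ids` (concept IDs in the train
#'   gold) and `unseen_ids` (test-only concept IDs).
#' @export
gen_corpus <- function(ont, spec) {
  surfaces <- surface_table(ont)
  if (is.null(surfaces) || !nrow(surfaces)) {
    stop("ontology offers no usable surfaces", call. = FALSE)
  }
  with_seed(spec$seed, {
    pool <- unique(surfaces$concept_id)
    n_unseen_wanted <- ceiling(spec$unseen_fraction * length(pool))
    train_pool <- if (n_unseen_wanted) {
      setdiff(pool, sample(pool, n_unseen_wanted))
    } else {
      pool
    }
    if (!length(train_pool)) {
      stop("unseen_fraction leaves no concepts for the training split",
           call. = FALSE)
    }
    # train split: sample concepts from the train pool only
    counts <- slot_counts(spec$n_docs, spec$sentences_per_doc,
                          spec$mention_rate, minimum = 1L)
    queue <- sample(train_pool, sum(counts), replace = TRUE)
    train <- assemble_docs(plan_split(queue, counts, surfaces, train_pool,
                                      spec),
                           "train")
    seen <- gold_ids(train)
    # unseen count u solves u >= f * (|seen| + u): every unseen concept is
    # planted at least once, so the used-concept tally is |seen| + u
    f <- spec$unseen_fraction
    u <- if (f > 0) ceiling(f * length(seen) / (1 - f)) else 0L
    candidates <- setdiff(pool, seen)
    if (u > length(candidates)) {
      stop(sprintf("unseen_fraction demands %d test-only concepts but only %d concepts are unused",
                   u, length(candidates)), call. = FALSE)
    }
    unseen <- if (u) sort(sample(candidates, u)) else character()
    counts <- slot_counts(spec$n_docs, spec$sentences_per_doc,
                          spec$mention_rate, minimum = max(1L, u))
    queue <- c(unseen, sample(seen, sum(counts) - u, replace = TRUE))
    queue <- sample(queue) # shuffle unseen plants across slots
    # test mentions may only involve already-seen or designated-unseen
    # concepts, so the test-only set is exactly `unseen`
    test <- assemble_docs(plan_split(queue, counts, surfaces,
                                     c(seen, unseen), spec),
                          "test")
    list(train = train, test = test, training_ids = seen,
         unseen_ids = unseen)
  })
}

#' The coordination worked example
#'
#' The canonical hard case for flattening: the phrase
#' `"ES and somatic cells"` carries a discontinuous annotation (fragments
#' `"ES"` and `"cells"`) that partially overlaps a contiguous annotation
#' (`"somatic cells"`).  Running all six unification x unnesting
#' combinations on it produces four distinct flattened sets, three of which
#' have lost one annotation entirely.
#'
#' @return `list(doc, annotations)` with two annotations under distinct
#'   concept IDs.
#' @export
coordination_example <- function() {
  doc <- document("coord", "ES and somatic cells")
  list(doc = doc, annotations = list(
    annotation("T1", "CL:0002322", list(c(0L, 2L), c(15L, 20L)), doc = doc),
    annotation("T2", "CL:0002371", c(7L, 20L), doc = doc)))
}
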