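# Readers and writers for brat-style standoff annotations, the package's
# CoNLL dialect, and an OBO 1.2 subset.  All files are UTF-8 with "\n" line
# endings; writers produce canonical output so that read(write(x)) == x.

read_lines_arg <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    readLines(x, encoding = "UTF-8", warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x, fixed = TRUE)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }
}

write_lines_arg <- function(lines, path) {
  if (is.null(path)) return(lines)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = FALSE)
  invisible(lines)
}

#' Read brat-style standoff annotations
#'
#' One annotation per `T` line, four tab-separated fields: annotation ID,
#' concept ID, fragment offsets (`start end` pairs separated by `;`), and
#' the covered text.  The covered text is verified against the document.
#'
#' @param x File path, a single string with embedded newlines, or a
#'   character vector of lines.
#' @param doc The [document()] the annotations anchor into.
#' @return A list of [annotation()] objects.
#' @export
read_standoff <- function(x, doc) {
  lines <- read_lines_arg(x)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line)) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 4L || !grepl("^T\\S*$", fields[[1L]])) {
      stop(sprintf("standoff parse error at line %d: expected 4 tab-separated fields starting with a T-id", ln),
           call. = FALSE)
    }
    frag_strs <- strsplit(fields[[3L]], ";", fixed = TRUE)[[1L]]
    spans <- lapply(frag_strs, function(f) {
      pair <- strsplit(trimws(f), "[[:space:]]+")[[1L]]
      vals <- suppressWarnings(as.integer(pair))
      if (length(vals) != 2L || anyNA(vals)) {
        stop(sprintf("standoff parse error at line %d: bad offset pair '%s'", ln, f),
             call. = FALSE)
      }
      vals
    })
    raw <- validate_spans(as_span_matrix(spans))
    if (any(raw[, "end"] > nchar(doc$text))) {
      stop(sprintf("standoff line %d: span beyond end of document %s",
                   ln, doc$doc_id), call. = FALSE)
    }
    seen <- paste(substring(doc$text, raw[, "start"] + 1L, raw[, "end"]),
                  collapse = " ")
    if (!identical(seen, fields[[4L]])) {
      stop(sprintf("annotation %s: covered text mismatch ('%s' in file, '%s' in document)",
                   fields[[1L]], fields[[4L]], seen), call. = FALSE)
    }
    out[[length(out) + 1L]] <- annotation(fields[[1L]], fields[[2L]], raw, doc = doc)
  }
  out
}

#' Write brat-style standoff annotations
#'
#' Inverse of [read_standoff()].  Lines are sorted by first span start, then
#' last span end, then concept ID, then annotation ID.
#'
#' @param anns List of [annotation()] objects.
#' @param doc Optional [document()] used to (re)derive covered texts.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_standoff <- function(anns, doc = NULL, path = NULL) {
  if (!length(anns)) return(write_lines_arg(character(), path))
  starts <- vapply(anns, function(a) a$spans[1L, "start"], 0L)
  ends <- vapply(anns, function(a) a$spans[nrow(a$spans), "end"], 0L)
  cids <- vapply(anns, `[[`, "", "concept_id")
  aids <- vapply(anns, `[[`, "", "ann_id")
  anns <- anns[order(starts, ends, cids, aids)]
  lines <- vapply(anns, function(a) {
    txt <- if (!is.null(doc)) covered_text(doc, a) else a$text
    if (is.null(txt)) {
      stop(sprintf("annotation %s has no text and no document was given", a$ann_id),
           call. = FALSE)
    }
    frags <- paste(sprintf("%d %d", a$spans[, "start"], a$spans[, "end"]),
                   collapse = ";")
    paste(a$ann_id, a$concept_id, frags, txt, sep = "\t")
  }, "")
  write_lines_arg(lines, path)
}

#' Read the CoNLL dialect
#'
#' Rows carry six tab-separated fields: `TOKEN START END DICT SPAN ID`.
#' `DICT` is `-` or a `|`-joined, lexically sorted, duplicate-free list of
#' concept IDs; `SPAN` is an IOBES tag; `ID` a concept ID or `NIL`.  A line
#' `# doc_id = X` starts a new document; blank lines (sentence breaks) are
#' tolerated and carry no information.
#'
#' @param x File path, string with newlines, or character vector of lines.
#' @return A list with one element per document: `list(doc_id, tokens)`
#'   where `tokens` is a labelled-token data frame.
#' @export
read_conll <- function(x) {
  lines <- read_lines_arg(x)
  docs <- list()
  cur_id <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(cur_id)) return()
    tok <- if (length(rows)) {
      data.frame(surface = vapply(rows, `[[`, "", 1L),
                 start = as.integer(vapply(rows, `[[`, "", 2L)),
                 end = as.integer(vapply(rows, `[[`, "", 3L)),
                 stringsAsFactors = FALSE)
    } else {
      tokenize("")
    }
    dict <- lapply(rows, function(r) {
      if (r[[4L]] == "-") character() else strsplit(r[[4L]], "|", fixed = TRUE)[[1L]]
    })
    docs[[length(docs) + 1L]] <<- list(
      doc_id = cur_id,
      tokens = labelled_tokens(tok,
                               span_tag = vapply(rows, `[[`, "", 5L),
                               id_tag = vapply(rows, `[[`, "", 6L),
                               dict = dict))
    rows <<- list()
  }
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line)) next
    if (grepl("^# doc_id = ", line)) {
      flush()
      cur_id <- sub("^# doc_id = ", "", line)
      next
    }
    if (is.null(cur_id)) {
      stop(sprintf("CoNLL parse error at line %d: token row before any '# doc_id =' header", ln),
           call. = FALSE)
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 6L) {
      stop(sprintf("CoNLL parse error at line %d: expected 6 fields, got %d",
                   ln, length(fields)), call. = FALSE)
    }
    if (!fields[[5L]] %in% SPAN_TAGS) {
      stop(sprintf("CoNLL parse error at line %d: unknown span tag '%s'",
                   ln, fields[[5L]]), call. = FALSE)
    }
    if (fields[[4L]] != "-") {
      ids <- strsplit(fields[[4L]], "|", fixed = TRUE)[[1L]]
      if (anyDuplicated(ids) || is.unsorted(ids, strictly = TRUE)) {
        stop(sprintf("CoNLL parse error at line %d: dict field must be sorted and duplicate-free", ln),
             call. = FALSE)
      }
    }
    if (suppressWarnings(anyNA(as.integer(fields[2:3])))) {
      stop(sprintf("CoNLL parse error at line %d: non-integer offsets", ln),
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- fields
  }
  flush()
  docs
}

#' Write the CoNLL dialect
#'
#' Inverse of [read_conll()]: `read_conll(write_conll(x))` is the identity.
#'
#' @param docs A list of `list(doc_id, tokens)` entries (as returned by
#'   [read_conll()]), or a single such entry.
#' @param path Optional output file.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_conll <- function(docs, path = NULL) {
  if (!is.null(docs$doc_id)) docs <- list(docs)
  lines <- character()
  for (d in docs) {
    lines <- c(lines, sprintf("# doc_id = %s", d$doc_id))
    tok <- d$tokens
    for (i in seq_len(nrow(tok))) {
      dict <- tok$dict[[i]]
      dict_field <- if (length(dict)) paste(sort(unique(dict)), collapse = "|") else "-"
      lines <- c(lines, paste(tok$surface[i], tok$start[i], tok$end[i],
                              dict_field, tok$span_tag[i], tok$id_tag[i],
                              sep = "\t"))
    }
  }
  write_lines_arg(lines, path)
}

#' Read an OBO 1.2 subset into an ontology
#'
#' Parses `[Term]` stanzas with `id:`, `name:`, `synonym: "..." ...` and
#' `is_a:` lines.  Obsolete stanzas (`is_obsolete: true`) are skipped; only
#' `is_a` relations are read.  After parsing, parent references are checked
#' and the graph must be acyclic.
#'
#' @param x File path, string with newlines, or character vector of lines.
#' @return A [ontology()].
#' @export
read_obo_lite <- function(x) {
  lines <- read_lines_arg(x)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (line in lines) {
    line <- sub("\\s+$", "", line)
    if (line == "[Term]") {
      flush()
      in_term <- TRUE
      cur <- list(synonyms = character(), parents = character())
      next
    }
    if (grepl("^\\[", line)) { # other stanza type ([Typedef] etc.)
      flush()
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(line)) next
    if (grepl("^id: ", line)) {
      cur$id <- sub("^id: ", "", line)
    } else if (grepl("^name: ", line)) {
      cur$name <- sub("^name: ", "", line)
    } else if (grepl("^synonym: ", line)) {
      m <- regmatches(line, regexec('^synonym: "([^"]*)"', line))[[1L]]
      if (length(m) < 2L) {
        stop(sprintf("OBO parse error: bad synonym line '%s'", line), call. = FALSE)
      }
      cur$synonyms <- c(cur$synonyms, m[[2L]])
    } else if (grepl("^is_a: ", line)) {
      target <- sub("\\s*!.*$", "", sub("^is_a: ", "", line))
      cur$parents <- c(cur$parents, target)
    } else if (grepl("^is_obsolete: true", line)) {
      cur$obsolete <- TRUE
    }
  }
  flush()
  ids <- vapply(terms, `[[`, "", "id")
  nms <- vapply(terms, function(t) if (is.null(t$name)) t$id else t$name, "")
  ontology(ids, nms,
           synonyms = lapply(terms, `[[`, "synonyms"),
           parents = lapply(terms, `[[`, "parents"))
}

#' Write an ontology as OBO
#'
#' Minimal writer covering the subset [read_obo_lite()] reads; useful for
#' exporting synthetic ontologies.
#'
#' @param ont A [ontology()].
#' @param path Optional output file.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_obo_lite <- function(ont, path = NULL) {
  lines <- c("format-version: 1.2", "")
  for (id in ont$ids) {
    lines <- c(lines, "[Term]", sprintf("id: %s", id),
               sprintf("name: %s", ont$name[[id]]))
    for (syn in setdiff(ont$synonyms[[id]], ont$name[[id]])) {
      lines <- c(lines, sprintf('synonym: "%s" EXACT []', syn))
    }
    for (p in ont$parents[[id]]) {
      lines <- c(lines, sprintf("is_a: %s ! %s", p, ont$name[[p]]))
    }
    lines <- c(lines, "")
  }
  write_lines_arg(lines, path)
}
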