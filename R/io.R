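# Interchange formats: BioC XML corpora (one document per evidence
# sentence, statements as annotation infons keyed "bel"), tab-separated
# submission and fragment tables, and the stage-2 entity annotation file
# with character offsets.

#' Read a BioC XML corpus of evidence sentences and BEL statements
#'
#' Expects the dialect written by [write_bioc_corpus()]: one document per
#' evidence record, a single sentence-level passage carrying an
#' `evidence_id` infon and a `pmid` infon, and one `<annotation>` per BEL
#' statement with the statement text in an infon keyed `"bel"`. Statement
#' strings are parsed with [parse_statement()]; parse failures are
#' collected (attribute `"parse_failures"`), never fatal.
#'
#' @param path Path to a BioC XML file.
#' @return A tibble with columns `evidence_id`, `pmid`, `sentence` and a
#'   `statements` list-column of character vectors (length 0 for unlabeled
#'   sentences), with a `parse_failures` attribute tibble
#'   (`evidence_id`, `statement`, `message`).
#' @export
read_bioc_corpus <- function(path) {
  doc <- xml2::read_xml(path)
  docs <- xml2::xml_find_all(doc, ".//document")
  failures <- tibble::tibble(evidence_id = character(),
                             statement = character(),
                             message = character())
  rows <- lapply(docs, function(d) {
    passage <- xml2::xml_find_first(d, ".//passage")
    if (is.na(passage)) {
      stop(sprintf("malformed BioC XML: document '%s' has no passage",
                   xml2::xml_text(xml2::xml_find_first(d, "./id"))),
           call. = FALSE)
    }
    eid <- xml2::xml_text(
      xml2::xml_find_first(passage, "./infon[@key='evidence_id']"))
    if (is.na(eid) || !nzchar(eid)) {
      eid <- xml2::xml_text(xml2::xml_find_first(d, "./id"))
    }
    pmid <- xml2::xml_text(
      xml2::xml_find_first(passage, "./infon[@key='pmid']"))
    sentence <- xml2::xml_text(xml2::xml_find_first(passage, "./text"))
    stmts <- xml2::xml_text(
      xml2::xml_find_all(passage, "./annotation/infon[@key='bel']"))
    for (s in stmts) {
      err <- tryCatch({ parse_statement(s); NULL },
                      bel_parse_error = function(e) e$bel_message)
      if (!is.null(err)) {
        failures <<- dplyr::bind_rows(failures, tibble::tibble(
          evidence_id = eid, statement = s, message = err))
      }
    }
    tibble::tibble(evidence_id = eid,
                   pmid = if (is.na(pmid)) "" else pmid,
                   sentence = if (is.na(sentence)) "" else sentence,
                   statements = list(stmts))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(evidence_id = character(), pmid = character(),
                          sentence = character(), statements = list())
  }
  attr(out, "parse_failures") <- failures
  out
}

#' Write evidence records to BioC XML
#'
#' Statements that parse are written in canonical spelling; unparseable
#' strings are written verbatim. [read_bioc_corpus()] on the output
#' reproduces the input records (statements in canonical form).
#'
#' @param records A tibble with columns `evidence_id`, `pmid`, `sentence`
#'   and a `statements` list-column (as from [read_bioc_corpus()]), or
#'   with a plain `statement` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bioc_corpus <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (!"statements" %in% names(records) && "statement" %in% names(records)) {
    records <- records |>
      dplyr::group_by(.data$evidence_id) |>
      dplyr::summarise(
        pmid = if ("pmid" %in% names(records)) dplyr::first(.data$pmid) else "",
        sentence = if ("sentence" %in% names(records))
          dplyr::first(.data$sentence) else "",
        statements = list(.data$statement), .groups = "drop")
  }
  doc <- xml2::xml_new_root("collection")
  xml2::xml_add_child(doc, "source", "belscore")
  xml2::xml_add_child(doc, "date", format(Sys.Date(), "%Y-%m-%d"))
  xml2::xml_add_child(doc, "key", "bel-statements.key")
  for (k in seq_len(nrow(records))) {
    d <- xml2::xml_add_child(doc, "document")
    xml2::xml_add_child(d, "id", records$evidence_id[[k]])
    p <- xml2::xml_add_child(d, "passage")
    inf <- xml2::xml_add_child(p, "infon", records$evidence_id[[k]])
    xml2::xml_set_attr(inf, "key", "evidence_id")
    pmid <- if ("pmid" %in% names(records)) records$pmid[[k]] else ""
    inf <- xml2::xml_add_child(p, "infon", pmid)
    xml2::xml_set_attr(inf, "key", "pmid")
    xml2::xml_add_child(p, "offset", "0")
    sent <- if ("sentence" %in% names(records)) records$sentence[[k]] else ""
    xml2::xml_add_child(p, "text", sent)
    stmts <- records$statements[[k]]
    for (j in seq_along(stmts)) {
      canon <- tryCatch(serialize_statement(parse_statement(stmts[[j]])),
                        bel_parse_error = function(e) stmts[[j]])
      a <- xml2::xml_add_child(p, "annotation")
      xml2::xml_set_attr(a, "id", as.character(j))
      inf <- xml2::xml_add_child(a, "infon", canon)
      xml2::xml_set_attr(inf, "key", "bel")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sub("\r$", "", lines)
}

#' Read a task-1 submission file
#'
#' Tab-separated lines `evidence_id<TAB>statement`. Raw statement lines
#' are preserved untouched; parsing and validation are deferred to
#' [evaluate_corpus()]. Blank lines are ignored; LF and CRLF both accepted.
#'
#' @param path Path to the submission TSV.
#' @return A tibble with columns `evidence_id`, `statement`.
#' @export
read_submission <- function(path) {
  lines <- read_tsv_lines(path)
  rows <- lapply(seq_along(lines), function(k) {
    line <- lines[[k]]
    if (!nzchar(trimws(line))) return(NULL)
    cells <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(cells) != 2L) {
      stop(sprintf("line %d: expected 2 tab-separated columns, found %d",
                   k, length(cells)), call. = FALSE)
    }
    tibble::tibble(evidence_id = cells[[1L]], statement = cells[[2L]])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(evidence_id = character(), statement = character())
  }
  out
}

#' Write a task-1 submission file
#'
#' @param corpus A data frame with columns `evidence_id`, `statement`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_submission <- function(corpus, path) {
  corpus <- as_corpus_df(corpus, "corpus")
  writeLines(paste(corpus$evidence_id, corpus$statement, sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

relation_fragment_text <- function(r) {
  paste(paste(vapply(r$subject_terms, serialize_node, character(1)),
              collapse = "+"),
        r$relation,
        paste(vapply(r$object_terms, serialize_node, character(1)),
              collapse = "+"))
}

#' Write the tab-separated fragment table of a corpus
#'
#' One row per fragment of every statement: columns `evidence_id`,
#' `fragment_kind` (`term`, `function`, `relation`, `statement`) and the
#' canonical fragment text. Complex members are emitted as separate term
#' rows.
#'
#' @param corpus A data frame with `evidence_id` and `statement` columns
#'   (or a `statements` list-column).
#' @param path Output path.
#' @return The fragment tibble, invisibly; `path` is written as TSV with a
#'   header.
#' @export
write_fragment_table <- function(corpus, path) {
  corpus <- as_corpus_df(corpus, "corpus")
  rows <- lapply(seq_len(nrow(corpus)), function(k) {
    s <- parse_statement(corpus$statement[[k]],
                         evidence_id = corpus$evidence_id[[k]])
    fb <- fragment_statement(s)
    tibble::tibble(
      evidence_id = corpus$evidence_id[[k]],
      fragment_kind = c(rep("term", length(fb$terms)),
                        rep("function", length(fb$functions)),
                        "relation", "statement"),
      fragment = c(vapply(fb$terms, serialize_node, character(1)),
                   vapply(fb$functions, function(f) serialize_node(f$node),
                          character(1)),
                   relation_fragment_text(fb$relation),
                   serialize_statement(s)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(evidence_id = character(),
                          fragment_kind = character(),
                          fragment = character())
  }
  writeLines(c("evidence_id\tfragment_kind\tfragment",
               paste(out$evidence_id, out$fragment_kind, out$fragment,
                     sep = "\t")),
             path, useBytes = TRUE)
  invisible(out)
}

#' Read a stage-2 entity annotation file
#'
#' Tab-separated with header columns `evidence_id`, `start`, `end`,
#' `surface`, `namespace`, `concept`. Offsets are 0-based, half-open, at
#' character granularity. When a corpus is supplied, each annotation's
#' offsets are checked against the evidence sentence:
#' `substr(sentence, start + 1, end)` must equal `surface`.
#'
#' @param path Path to the annotation TSV.
#' @param corpus Optional corpus tibble with `evidence_id` and `sentence`
#'   columns for offset verification.
#' @return A tibble with the six columns, `start`/`end` as integers.
#' @export
read_entity_annotations <- function(path, corpus = NULL) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(evidence_id = character(), start = integer(),
                          end = integer(), surface = character(),
                          namespace = character(), concept = character()))
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  want <- c("evidence_id", "start", "end", "surface", "namespace", "concept")
  if (!identical(tolower(header), want)) {
    stop("line 1: expected header: ", paste(want, collapse = "\t"),
         call. = FALSE)
  }
  rows <- lapply(seq_along(lines)[-1L], function(k) {
    cells <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != 6L) {
      stop(sprintf("line %d: expected 6 tab-separated columns, found %d",
                   k, length(cells)), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(cells[[2L]]))
    end <- suppressWarnings(as.integer(cells[[3L]]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("line %d: non-integer offsets", k), call. = FALSE)
    }
    if (!(start >= 0L && end > start)) {
      stop(sprintf("line %d: invalid offsets [%d, %d)", k, start, end),
           call. = FALSE)
    }
    ns <- toupper(cells[[5L]])
    if (!ns %in% BEL_NAMESPACES) {
      stop(sprintf("line %d: unknown namespace '%s'", k, cells[[5L]]),
           call. = FALSE)
    }
    tibble::tibble(evidence_id = cells[[1L]], start = start, end = end,
                   surface = cells[[4L]], namespace = ns,
                   concept = cells[[6L]])
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(corpus)) {
    stopifnot(all(c("evidence_id", "sentence") %in% names(corpus)))
    for (k in seq_len(nrow(out))) {
      idx <- match(out$evidence_id[[k]], corpus$evidence_id)
      if (is.na(idx)) {
        stop(sprintf("annotation for unknown evidence_id '%s'",
                     out$evidence_id[[k]]), call. = FALSE)
      }
      sent <- corpus$sentence[[idx]]
      if (out$end[[k]] > nchar(sent)) {
        stop(sprintf("evidence_id '%s': offsets [%d, %d) exceed sentence length %d",
                     out$evidence_id[[k]], out$start[[k]], out$end[[k]],
                     nchar(sent)), call. = FALSE)
      }
      got <- substr(sent, out$start[[k]] + 1L, out$end[[k]])
      if (!identical(got, out$surface[[k]])) {
        stop(sprintf(
          "evidence_id '%s': surface mismatch at [%d, %d): expected '%s', sentence has '%s'",
          out$evidence_id[[k]], out$start[[k]], out$end[[k]],
          out$surface[[k]], got), call. = FALSE)
      }
    }
  }
  out
}
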