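# Cascade scorer: predictions are compared with gold statements per
# evidence sentence at six levels (Term, Function, Function-Secondary,
# Relation, Relation-Secondary, Statement). Credit at each level is the
# size of a maximum bipartite matching between deduplicated gold and
# predicted fragments under that level's equivalence predicate; counts are
# micro-averaged over the corpus.

BEL_LEVELS <- c("Term", "Function", "Function-Secondary",
                "Relation", "Relation-Secondary", "Statement")

# Kuhn's augmenting-path maximum bipartite matching. adj[[i]] lists the
# right-side vertices compatible with left (gold) vertex i.
kuhn_matching <- function(adj, n_right) {
  match_right <- rep(NA_integer_, n_right)
  dfs <- function(i, seen) {
    for (j in adj[[i]]) {
      if (!seen[[j]]) {
        seen[[j]] <- TRUE
        if (is.na(match_right[[j]])) {
          match_right[[j]] <<- i
          return(list(found = TRUE, seen = seen))
        }
        res <- dfs(match_right[[j]], seen)
        seen <- res$seen
        if (res$found) {
          match_right[[j]] <<- i
          return(list(found = TRUE, seen = seen))
        }
      }
    }
    list(found = FALSE, seen = seen)
  }
  size <- 0L
  for (i in seq_along(adj)) {
    if (n_right == 0L) break
    res <- dfs(i, rep(FALSE, n_right))
    if (res$found) size <- size + 1L
  }
  size
}

default_fragment_predicate <- function(example, map, strict_tloc) {
  if (is.character(example)) {
    return(function(a, b) identical(a, b))
  }
  if (inherits(example, "bel_statement")) {
    return(function(a, b) statements_equivalent(a, b, map, strict_tloc))
  }
  if (is_bel_term(example)) {
    return(function(a, b) terms_equivalent(a, b, map))
  }
  if (is_bel_fn(example) ||
      (is.list(example) && !is.null(example$ftype))) {
    return(function(a, b) functions_equivalent(a, b, map, strict_tloc))
  }
  if (is.list(example) && !is.null(example$subject_terms)) {
    return(function(a, b) relation_match_count(a, b, map) == 3L)
  }
  stop("cannot infer an equivalence predicate for these fragments",
       call. = FALSE)
}

#' Match gold against predicted fragments at one cascade level
#'
#' Computes TP/FP/FN for one evidence unit: TP is the size of a maximum
#' bipartite matching between the gold and predicted fragment sets under
#' the level's equivalence predicate (so credit never depends on input
#' order when equivalence classes overlap), FN = |gold| - TP and
#' FP = |pred| - TP. The predicate is inferred from the fragment type
#' (terms, function fragments, relation fragments, statements, or bare
#' function-type strings) unless supplied explicitly.
#'
#' @param gold,pred Lists of fragments of one kind, deduplicated within the
#'   evidence unit.
#' @param map Optional `bel_equivalence_map`.
#' @param predicate Optional `function(gold_fragment, pred_fragment)`
#'   returning a logical.
#' @param strict_tloc Require tloc() locations to match.
#' @return A tibble with columns `tp`, `fp`, `fn`.
#' @examples
#' gold <- lapply(c("p(HGNC:IL1B)", "p(HGNC:ATF2)"), parse_term)
#' pred <- lapply(c("p(HGNC:IL1B)"), parse_term)
#' match_fragments(gold, pred)
#' @export
match_fragments <- function(gold, pred, map = NULL, predicate = NULL,
                            strict_tloc = FALSE) {
  if (is.character(gold)) gold <- as.list(gold)
  if (is.character(pred)) pred <- as.list(pred)
  n_g <- length(gold)
  n_p <- length(pred)
  if (n_g == 0L || n_p == 0L) {
    return(tibble::tibble(tp = 0L, fp = n_p, fn = n_g))
  }
  if (is.null(predicate)) {
    predicate <- default_fragment_predicate(gold[[1L]], map, strict_tloc)
  }
  adj <- lapply(gold, function(g) {
    which(vapply(pred, function(p) isTRUE(predicate(g, p)), logical(1)))
  })
  tp <- kuhn_matching(adj, n_p)
  tibble::tibble(tp = tp, fp = n_p - tp, fn = n_g - tp)
}

dedup_by_key <- function(items, keys) items[!duplicated(keys)]

# Merge the fragment bundles of all statements of one evidence unit and
# deduplicate each fragment kind by its canonical identity key.
evidence_fragments <- function(statements) {
  bundles <- lapply(statements, fragment_statement)
  terms <- unlist(lapply(bundles, `[[`, "terms"), recursive = FALSE)
  fns <- unlist(lapply(bundles, `[[`, "functions"), recursive = FALSE)
  relations <- lapply(bundles, `[[`, "relation")
  stmts <- lapply(bundles, `[[`, "statement")
  list(
    Term = dedup_by_key(terms, vapply(terms, term_frag_key, character(1))),
    Function = dedup_by_key(fns, vapply(fns, fn_frag_key, character(1))),
    `Function-Secondary` = as.list(unique(
      unlist(lapply(bundles, `[[`, "secondary_functions")))),
    Relation = dedup_by_key(
      relations, vapply(relations, relation_frag_key, character(1))),
    Statement = dedup_by_key(
      stmts, vapply(stmts, statement_frag_key, character(1)))
  )
}

level_counts <- function(gold_frags, pred_frags, map, strict_tloc) {
  counts <- list(
    Term = match_fragments(gold_frags$Term, pred_frags$Term, map),
    Function = match_fragments(
      gold_frags$Function, pred_frags$Function, map,
      predicate = function(a, b) functions_equivalent(a, b, map, strict_tloc)),
    `Function-Secondary` = match_fragments(
      unlist(gold_frags$`Function-Secondary`),
      unlist(pred_frags$`Function-Secondary`)),
    Relation = match_fragments(
      gold_frags$Relation, pred_frags$Relation, map,
      predicate = function(a, b) relation_match_count(a, b, map) == 3L),
    `Relation-Secondary` = match_fragments(
      gold_frags$Relation, pred_frags$Relation, map,
      predicate = function(a, b) relation_match_count(a, b, map) >= 2L),
    Statement = match_fragments(
      gold_frags$Statement, pred_frags$Statement, map,
      predicate = function(a, b) statements_equivalent(a, b, map, strict_tloc))
  )
  dplyr::bind_rows(counts, .id = "level")
}

as_corpus_df <- function(x, arg = "corpus") {
  if (inherits(x, "data.frame")) {
    x <- tibble::as_tibble(x)
    if (!"evidence_id" %in% names(x)) {
      stop(sprintf("%s must have an 'evidence_id' column", arg), call. = FALSE)
    }
    if ("statement" %in% names(x)) {
      return(dplyr::select(x, "evidence_id", "statement"))
    }
    if ("statements" %in% names(x)) {
      out <- tidyr::unnest(
        dplyr::select(x, "evidence_id", statement = "statements"),
        "statement")
      return(dplyr::filter(out, !is.na(.data$statement)))
    }
    stop(sprintf("%s must have a 'statement' or 'statements' column", arg),
         call. = FALSE)
  }
  stop(sprintf("%s must be a data frame", arg), call. = FALSE)
}

#' Evaluate a prediction corpus against a gold corpus at all cascade levels
#'
#' Scores predicted BEL statements against the gold standard per evidence
#' sentence and micro-averages TP/FP/FN over the corpus at six levels:
#' Term, Function, Function-Secondary, Relation, Relation-Secondary and
#' full Statement. Predicted statements that fail [validate_statement()]
#' are ignored (they contribute to no count); fragments are deduplicated
#' within each evidence unit; matching applies the track's equivalence
#' simplifications.
#'
#' @param gold,pred Data frames with columns `evidence_id` and `statement`
#'   (or a `statements` list-column as produced by [read_bioc_corpus()]).
#'   `pred` rows with an `evidence_id` absent from the gold corpus raise a
#'   warning and count as false-positive sources.
#' @param map Optional `bel_equivalence_map` for cross-namespace gene
#'   matching.
#' @param strict_tloc Require tloc() locations to match (default: locations
#'   are ignored).
#' @param macro Also report macro-averaged scores (mean of per-evidence
#'   precision/recall/F); micro-averaged scores are always reported.
#' @return A `bel_evaluation` object; see [tidy.bel_evaluation()] for the
#'   per-level tibble, `glance()` for a one-row summary, and
#'   [autoplot.bel_evaluation()] for a plot. Slots: `levels` (per-level
#'   counts and scores), `ignored_invalid` (number of ignored predicted
#'   statements), `invalid` (their records), `no_correct` (per level, the
#'   number of evidence sentences with gold fragments but zero true
#'   positives), `per_evidence` (per-evidence counts), `macro`.
#' @examples
#' gold <- tibble::tibble(evidence_id = "e1",
#'   statement = "p(HGNC:IL1B) increases p(HGNC:ATF2, pmod(P))")
#' pred <- tibble::tibble(evidence_id = "e1",
#'   statement = "p(HGNC:IL1B) decreases p(HGNC:ATF2)")
#' tidy(evaluate_corpus(gold, pred))
#' @export
evaluate_corpus <- function(gold, pred, map = NULL, strict_tloc = FALSE,
                            macro = FALSE) {
  gold <- as_corpus_df(gold, "gold")
  pred <- as_corpus_df(pred, "pred")

  gold_parsed <- lapply(seq_len(nrow(gold)), function(k) {
    v <- validate_statement(gold$statement[[k]])
    if (!v$valid) {
      stop(sprintf("invalid gold statement for evidence '%s': %s",
                   gold$evidence_id[[k]], v$errors$message[[1L]]),
           call. = FALSE)
    }
    v$statement
  })

  invalid <- tibble::tibble(evidence_id = character(),
                            statement = character(),
                            message = character())
  pred_parsed <- vector("list", nrow(pred))
  keep <- logical(nrow(pred))
  for (k in seq_len(nrow(pred))) {
    v <- validate_statement(pred$statement[[k]])
    if (v$valid) {
      pred_parsed[[k]] <- v$statement
      keep[k] <- TRUE
    } else {
      invalid <- dplyr::bind_rows(invalid, tibble::tibble(
        evidence_id = pred$evidence_id[[k]],
        statement = pred$statement[[k]],
        message = paste(v$errors$message, collapse = "; ")))
    }
  }

  orphan <- setdiff(unique(pred$evidence_id[keep]), unique(gold$evidence_id))
  if (length(orphan) > 0L) {
    warning(sprintf(
      "%d prediction evidence_id(s) absent from the gold corpus (counted as false-positive sources): %s",
      length(orphan), paste(utils::head(orphan, 5L), collapse = ", ")),
      call. = FALSE)
  }

  evidence_ids <- union(unique(gold$evidence_id), unique(pred$evidence_id[keep]))
  per_evidence <- vector("list", length(evidence_ids))
  for (k in seq_along(evidence_ids)) {
    eid <- evidence_ids[[k]]
    g_stmts <- gold_parsed[gold$evidence_id == eid]
    p_stmts <- pred_parsed[pred$evidence_id == eid & keep]
    gf <- evidence_fragments(g_stmts)
    pf <- evidence_fragments(p_stmts)
    counts <- level_counts(gf, pf, map, strict_tloc)
    counts$evidence_id <- eid
    per_evidence[[k]] <- counts
  }
  per_evidence <- if (length(per_evidence) > 0L) {
    dplyr::bind_rows(per_evidence)
  } else {
    tibble::tibble(level = character(), tp = integer(), fp = integer(),
                   fn = integer(), evidence_id = character())
  }

  totals <- per_evidence |>
    dplyr::group_by(level = factor(.data$level, levels = BEL_LEVELS)) |>
    dplyr::summarise(tp = sum(.data$tp), fp = sum(.data$fp),
                     fn = sum(.data$fn), .groups = "drop") |>
    tidyr::complete(level, fill = list(tp = 0L, fp = 0L, fn = 0L)) |>
    dplyr::mutate(level = as.character(.data$level))
  levels_tbl <- precision_recall_f(totals)

  if (macro) {
    macro_tbl <- per_evidence |>
      precision_recall_f() |>
      dplyr::group_by(level = factor(.data$level, levels = BEL_LEVELS)) |>
      dplyr::summarise(precision = mean(.data$precision),
                       recall = mean(.data$recall),
                       f_score = mean(.data$f_score), .groups = "drop") |>
      dplyr::mutate(level = as.character(.data$level))
  } else {
    macro_tbl <- NULL
  }

  no_correct <- per_evidence |>
    dplyr::group_by(level = factor(.data$level, levels = BEL_LEVELS)) |>
    dplyr::summarise(
      sentences = sum(.data$tp == 0L & (.data$tp + .data$fn) > 0L),
      .groups = "drop") |>
    tidyr::complete(level, fill = list(sentences = 0L)) |>
    dplyr::mutate(level = as.character(.data$level))

  structure(list(
    levels = levels_tbl,
    macro_levels = macro_tbl,
    ignored_invalid = nrow(invalid),
    invalid = invalid,
    no_correct = no_correct,
    per_evidence = per_evidence,
    macro = macro
  ), class = "bel_evaluation")
}

#' Compute precision, recall and F-score from TP/FP/FN counts
#'
#' Micro scores from raw counts: P = tp/(tp+fp), R = tp/(tp+fn), and
#' F = 2PR/(P+R), each defined as 0 when its denominator is 0.
#'
#' @param counts A data frame with numeric columns `tp`, `fp`, `fn`
#'   (e.g. from [match_fragments()]); extra columns are passed through.
#' @return The input tibble with `precision`, `recall` and `f_score`
#'   columns added (fractions in \[0, 1\]).
#' @examples
#' precision_recall_f(tibble::tibble(tp = 117, fp = 265, fn = 100))
#' @export
precision_recall_f <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn") %in% names(counts)))
  tibble::as_tibble(counts) |>
    dplyr::mutate(
      precision = ifelse(.data$tp + .data$fp > 0,
                         .data$tp / (.data$tp + .data$fp), 0),
      recall = ifelse(.data$tp + .data$fn > 0,
                      .data$tp / (.data$tp + .data$fn), 0),
      f_score = ifelse(.data$precision + .data$recall > 0,
                       2 * .data$precision * .data$recall /
                         (.data$precision + .data$recall), 0))
}

# Round half away from zero, the convention of the track's printed tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

percent2 <- function(x) sprintf("%.2f", round_half_up(100 * x, 2))

#' Format an evaluation report as a fixed-width table
#'
#' Renders per-level F, P and R (in that column order) as percentages with
#' two decimals, rounded half up, one row per cascade level.
#'
#' @param r A `bel_evaluation` from [evaluate_corpus()].
#' @return A character vector of table lines (invisibly printed with
#'   `cat()` when autoprinted).
#' @export
format_report <- function(r) {
  stopifnot(inherits(r, "bel_evaluation"))
  rows <- r$levels
  lines <- c(
    sprintf("%-20s %8s %8s %8s %6s %6s %6s",
            "Level", "F", "P", "R", "TP", "FP", "FN"),
    vapply(seq_len(nrow(rows)), function(k) {
      sprintf("%-20s %8s %8s %8s %6d %6d %6d",
              rows$level[[k]], percent2(rows$f_score[[k]]),
              percent2(rows$precision[[k]]), percent2(rows$recall[[k]]),
              rows$tp[[k]], rows$fp[[k]], rows$fn[[k]])
    }, character(1))
  )
  if (r$ignored_invalid > 0L) {
    lines <- c(lines, sprintf("ignored invalid predicted statements: %d",
                              r$ignored_invalid))
  }
  lines
}

#' @export
print.bel_evaluation <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
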