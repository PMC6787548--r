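# Seeded synthetic gold/prediction corpus generator. Defaults emulate the
# composition of the 2017 test corpus: the increases:decreases ratio is
# 130:68, term classes follow the p/a/bp/path proportions 328:52:23:2, and
# per-statement function rates follow the act/pmod/complex/tloc/deg counts
# over 198 statements. Each statement carries at most one function node and
# all leaf entities within a statement are distinct, which keeps the
# analytic expected counts of perturb() exact.

ERROR_KINDS <- c("entity_swap", "namespace_swap", "relation_flip",
                 "subject_object_swap", "function_drop", "function_add",
                 "abundance_change", "invalidate_syntax", "drop_statement")

DEFAULT_FUNCTION_RATES <- c(act = 79, pmod_P = 36, tloc = 10, deg = 4,
                            complex = 5) / 198

DEFAULT_TERM_CLASS_PROBS <- c(p = 328, a = 52, bp = 23, path = 2) / 405

GENE_NS_PROBS <- c(HGNC = 0.7, MGI = 0.2, EGID = 0.1)

synthetic_entity <- function(namespace, index) {
  value <- switch(namespace,
    HGNC = sprintf("GENE%d", index),
    MGI = sprintf("Gene%d", index),
    EGID = sprintf("%d", 10000L + index),
    CHEBI = sprintf("chemical-%d", index),
    GOBP = sprintf("process %d", index),
    MESHD = sprintf("Disease%d", index),
    GOCC = sprintf("compartment%d", index))
  bel_entity(namespace, value)
}

slot_term <- function(class, index) {
  switch(class,
    p = bel_term("p", entity = synthetic_entity(
      sample(names(GENE_NS_PROBS), 1L, prob = GENE_NS_PROBS), index)),
    a = bel_term("a", entity = synthetic_entity("CHEBI", index)),
    bp = bel_term("bp", entity = synthetic_entity("GOBP", index)),
    path = bel_term("path", entity = synthetic_entity("MESHD", index)))
}

#' Generate a seeded synthetic gold corpus of BEL statements
#'
#' Draws `n_statements` valid statements, one per synthetic evidence
#' sentence. Relation types, term classes and function rates default to
#' the composition of the track's 2017 test corpus; functions (including
#' complex formation) are applied to protein slots only and at most one
#' function node is generated per statement. Identical seeds yield
#' identical corpora.
#'
#' @param n_statements Number of statements (>= 1).
#' @param vocab_size Identifiers available per namespace; must be at least
#'   5 so every leaf entity within a statement (plus a swap reserve) is
#'   distinct.
#' @param function_rates Named per-statement probabilities for
#'   `act`, `pmod_P`, `tloc`, `deg` and `complex`; their sum must be <= 1.
#' @param p_increases Probability of the `increases` relation type.
#' @param term_class_probs Named probabilities for term classes
#'   `p`, `a`, `bp`, `path`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble with columns `evidence_id`, `pmid`, `sentence`,
#'   `statement` (canonical spelling).
#' @examples
#' generate_corpus(3, seed = 7)
#' @export
generate_corpus <- function(n_statements, vocab_size = 50,
                            function_rates = DEFAULT_FUNCTION_RATES,
                            p_increases = 130 / 198,
                            term_class_probs = DEFAULT_TERM_CLASS_PROBS,
                            seed = NULL) {
  stopifnot(n_statements >= 1)
  if (vocab_size < 5) {
    stop("vocab_size must be at least 5 to keep statement entities distinct",
         call. = FALSE)
  }
  function_rates <- function_rates[names(function_rates) %in%
                                     names(DEFAULT_FUNCTION_RATES)]
  if (sum(function_rates) > 1 + 1e-12) {
    stop("function_rates must sum to at most 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_statements)
  for (i in seq_len(n_statements)) {
    relation <- if (stats::runif(1) < p_increases) "increases" else "decreases"
    classes <- sample(names(term_class_probs), 2L, replace = TRUE,
                      prob = term_class_probs)
    # distinct identifier indices for every leaf this statement can hold
    idx <- sample.int(vocab_size, 4L)
    subject <- slot_term(classes[[1L]], idx[[1L]])
    object <- slot_term(classes[[2L]], idx[[2L]])

    u <- stats::runif(1)
    cum <- cumsum(function_rates)
    kind <- names(function_rates)[which(u < cum)[1L]]
    if (!is.na(kind) && !is.null(kind)) {
      protein_slots <- c("subject", "object")[c(classes[[1L]] == "p",
                                                classes[[2L]] == "p")]
      if (length(protein_slots) > 0L) {
        slot <- if (length(protein_slots) == 1L) protein_slots else
          sample(protein_slots, 1L)
        base <- if (slot == "subject") subject else object
        wrapped <- switch(kind,
          act = bel_fn("act", base),
          pmod_P = bel_fn("pmod_P", base),
          tloc = bel_fn("tloc", base,
                        from_loc = synthetic_entity("GOCC", 1L),
                        to_loc = synthetic_entity("GOCC", 2L)),
          deg = bel_fn("deg", base),
          complex = bel_term("complex", members = list(
            base,
            bel_term("p", entity = synthetic_entity(
              sample(names(GENE_NS_PROBS), 1L, prob = GENE_NS_PROBS),
              idx[[3L]])))))
        if (slot == "subject") subject <- wrapped else object <- wrapped
      }
    }
    s <- bel_statement(subject, relation, object)
    eid <- sprintf("ev%05d", i)
    rows[[i]] <- tibble::tibble(
      evidence_id = eid,
      pmid = sprintf("%d", 30000000L + i),
      sentence = sprintf("Synthetic evidence sentence %d.", i),
      statement = serialize_statement(s))
  }
  dplyr::bind_rows(rows)
}

# ---- typed error injection ---------------------------------------------

statement_leaves <- function(node, in_complex = FALSE, under_fn = FALSE) {
  if (is_bel_fn(node)) {
    return(statement_leaves(node$inner, in_complex, under_fn = TRUE))
  }
  if (!is.null(node$members)) {
    return(unlist(lapply(node$members, statement_leaves, in_complex = TRUE,
                         under_fn = under_fn),
                  recursive = FALSE))
  }
  list(list(term = node, in_complex = in_complex, under_fn = under_fn))
}

used_indices <- function(s) {
  leaves <- c(statement_leaves(s$subject), statement_leaves(s$object))
  idx <- vapply(leaves, function(l) {
    e <- l$term$entity
    raw <- suppressWarnings(as.integer(gsub("[^0-9]", "", e$value)))
    if (is.na(raw)) return(NA_integer_)
    if (e$namespace == "EGID") raw - 10000L else raw
  }, integer(1))
  unique(idx[!is.na(idx)])
}

replace_leaf <- function(node, target, replacement) {
  if (identical(node, target)) return(replacement)
  if (is_bel_fn(node)) {
    node$inner <- replace_leaf(node$inner, target, replacement)
    return(node)
  }
  if (!is.null(node$members)) {
    node$members <- lapply(node$members, replace_leaf, target = target,
                           replacement = replacement)
    return(node)
  }
  node
}

drop_first_function <- function(node) {
  if (is_bel_fn(node)) return(list(node = node$inner, dropped = TRUE))
  if (!is.null(node$members)) {
    for (k in seq_along(node$members)) {
      res <- drop_first_function(node$members[[k]])
      if (res$dropped) {
        node$members[[k]] <- res$node
        return(list(node = node, dropped = TRUE))
      }
    }
  }
  list(node = node, dropped = FALSE)
}

# Leaf slots eligible for an added act(): a bare simple protein term.
bare_protein_slot <- function(node) {
  is_bel_term(node) && is.null(node$members) && node$abundance == "p"
}

zero_deltas <- function() {
  stats::setNames(rep(0L, 12L), c(
    "term_fn", "term_fp", "fn_fn", "fn_fp", "fsec_fn", "fsec_fp",
    "rel_fn", "rel_fp", "relsec_fn", "relsec_fp", "stmt_fn", "stmt_fp"))
}

# The level-semantics table: per-level (fn, fp) deltas of one applied
# error, given the structural flags logged at perturbation time. This is
# the analytic counterpart the evaluator is checked against; it never
# calls the matcher.
error_deltas <- function(kind, n_terms = 0L, n_functions = 0L,
                         target_in_complex = FALSE,
                         target_under_fn = FALSE,
                         added_duplicate_ftype = FALSE) {
  d <- zero_deltas()
  switch(kind,
    none = d,
    abundance_change = d,
    entity_swap = ,
    namespace_swap = {
      d["term_fn"] <- d["term_fp"] <- 1L
      if (target_under_fn) d["fn_fn"] <- d["fn_fp"] <- 1L
      if (!target_in_complex) {
        d["rel_fn"] <- d["rel_fp"] <- 1L
        d["stmt_fn"] <- d["stmt_fp"] <- 1L
      }
      d
    },
    relation_flip = {
      d["rel_fn"] <- d["rel_fp"] <- 1L
      d["stmt_fn"] <- d["stmt_fp"] <- 1L
      d
    },
    subject_object_swap = {
      d["rel_fn"] <- d["rel_fp"] <- 1L
      d["relsec_fn"] <- d["relsec_fp"] <- 1L
      d["stmt_fn"] <- d["stmt_fp"] <- 1L
      d
    },
    function_drop = {
      d["fn_fn"] <- 1L
      d["fsec_fn"] <- 1L
      d["stmt_fn"] <- d["stmt_fp"] <- 1L
      d
    },
    function_add = {
      d["fn_fp"] <- 1L
      if (!added_duplicate_ftype) d["fsec_fp"] <- 1L
      d["stmt_fn"] <- d["stmt_fp"] <- 1L
      d
    },
    invalidate_syntax = ,
    drop_statement = {
      d["term_fn"] <- n_terms
      d["fn_fn"] <- n_functions
      d["fsec_fn"] <- n_functions
      d["rel_fn"] <- 1L
      d["relsec_fn"] <- 1L
      d["stmt_fn"] <- 1L
      d
    },
    stop(sprintf("unknown error_kind '%s'", kind), call. = FALSE)
  )
}

#' Perturb a gold corpus with typed, rate-controlled prediction errors
#'
#' Produces a prediction corpus by applying at most one typed error per
#' statement, each kind firing independently with its rate (rates must sum
#' to at most 1), together with a perturbation log and the analytically
#' expected per-level TP/FP/FN the evaluator must reproduce. Expected
#' counts derive from the realized log, not the nominal rates, so the
#' agreement is exact, not statistical. Errors that do not apply to a
#' statement (e.g. `function_drop` on a function-free statement,
#' `namespace_swap` without a gene term) are logged as `none`.
#'
#' @param corpus A gold corpus from [generate_corpus()] (or any tibble
#'   with `evidence_id` and valid `statement` columns, one statement per
#'   evidence, distinct leaf entities per statement).
#' @param error_kind Character vector of error kinds among
#'   `entity_swap`, `namespace_swap`, `relation_flip`,
#'   `subject_object_swap`, `function_drop`, `function_add`,
#'   `abundance_change`, `invalidate_syntax`, `drop_statement`.
#' @param rate Numeric vector of per-statement rates, recycled against
#'   `error_kind`; `sum(rate)` must be <= 1.
#' @param vocab_size The generator's vocabulary size (bounds replacement
#'   identifiers for `entity_swap`).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list with `pred` (prediction corpus tibble), `log` (one row
#'   per statement: `evidence_id`, `error_kind`, baseline fragment counts
#'   and structure flags) and `expected` (per-level expected counts from
#'   [expected_counts()]).
#' @examples
#' gold <- generate_corpus(5, seed = 1)
#' perturbed <- perturb(gold, "relation_flip", 1, seed = 2)
#' perturbed$expected
#' @export
perturb <- function(corpus, error_kind, rate, vocab_size = 50, seed = NULL) {
  corpus <- as_corpus_df(corpus, "corpus")
  stopifnot(length(error_kind) >= 1L)
  bad <- setdiff(error_kind, ERROR_KINDS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown error_kind '%s'", bad[[1L]]), call. = FALSE)
  }
  rate <- rep_len(rate, length(error_kind))
  stopifnot(all(rate >= 0), all(rate <= 1))
  if (sum(rate) > 1 + 1e-12) {
    stop("error rates must sum to at most 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cum <- cumsum(rate)
  pred_rows <- vector("list", nrow(corpus))
  log_rows <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    s <- parse_statement(corpus$statement[[i]],
                         evidence_id = corpus$evidence_id[[i]])
    fb <- fragment_statement(s)
    n_terms <- length(fb$terms)
    n_functions <- length(fb$functions)
    u <- stats::runif(1)
    hit <- which(u < cum)[1L]
    kind <- if (is.na(hit)) "none" else error_kind[[hit]]
    res <- apply_error(s, kind, vocab_size)
    log_rows[[i]] <- tibble::tibble(
      evidence_id = corpus$evidence_id[[i]],
      error_kind = res$kind,
      n_terms = n_terms,
      n_functions = n_functions,
      target_in_complex = res$target_in_complex,
      target_under_fn = res$target_under_fn,
      added_duplicate_ftype = res$added_duplicate_ftype)
    if (!is.null(res$text)) {
      pred_rows[[i]] <- tibble::tibble(
        evidence_id = corpus$evidence_id[[i]], statement = res$text)
    }
  }
  pred <- dplyr::bind_rows(pred_rows)
  if (nrow(pred) == 0L) {
    pred <- tibble::tibble(evidence_id = character(), statement = character())
  }
  log <- dplyr::bind_rows(log_rows)
  list(pred = pred, log = log, expected = expected_counts(log))
}

apply_error <- function(s, kind, vocab_size) {
  out <- list(kind = kind, text = NULL, target_in_complex = FALSE,
              target_under_fn = FALSE, added_duplicate_ftype = FALSE)
  none <- function() {
    out$kind <- "none"
    out$text <- serialize_statement(s)
    out
  }
  if (kind == "none") return(none())
  if (kind == "drop_statement") return(out)
  if (kind == "invalidate_syntax") {
    txt <- serialize_statement(s)
    out$text <- sub("\\)", "", txt)  # drop one closing parenthesis
    return(out)
  }
  if (kind == "relation_flip") {
    s$relation <- if (s$relation == "increases") "decreases" else "increases"
    out$text <- serialize_statement(s)
    return(out)
  }
  if (kind == "subject_object_swap") {
    tmp <- s$subject
    s$subject <- s$object
    s$object <- tmp
    out$text <- serialize_statement(s)
    return(out)
  }
  if (kind == "function_drop") {
    sub_res <- drop_first_function(s$subject)
    if (sub_res$dropped) {
      s$subject <- sub_res$node
    } else {
      obj_res <- drop_first_function(s$object)
      if (!obj_res$dropped) return(none())
      s$object <- obj_res$node
    }
    out$text <- serialize_statement(s)
    return(out)
  }
  if (kind == "function_add") {
    slot <- if (bare_protein_slot(s$subject)) "subject"
            else if (bare_protein_slot(s$object)) "object"
            else return(none())
    existing <- vapply(c(collect_function_nodes(s$subject),
                         collect_function_nodes(s$object)),
                       fragment_ftype, character(1))
    out$added_duplicate_ftype <- "act" %in% existing
    if (slot == "subject") s$subject <- bel_fn("act", s$subject)
    else s$object <- bel_fn("act", s$object)
    out$text <- serialize_statement(s)
    return(out)
  }
  # leaf-targeted errors
  leaves <- c(statement_leaves(s$subject), statement_leaves(s$object))
  eligible <- if (kind == "entity_swap") {
    leaves
  } else {
    Filter(function(l) is_gene_term(l$term), leaves)
  }
  if (length(eligible) == 0L) return(none())
  target <- eligible[[sample.int(length(eligible), 1L)]]
  out$target_in_complex <- target$in_complex
  out$target_under_fn <- target$under_fn
  new_term <- target$term
  if (kind == "entity_swap") {
    free <- setdiff(seq_len(vocab_size), used_indices(s))
    if (length(free) == 0L) {
      stop("vocab_size too small to draw a replacement entity", call. = FALSE)
    }
    new_idx <- free[[sample.int(length(free), 1L)]]
    new_term$entity <- synthetic_entity(new_term$entity$namespace, new_idx)
  } else if (kind == "namespace_swap") {
    ns <- new_term$entity$namespace
    new_ns <- switch(ns, HGNC = "MGI", MGI = "HGNC", EGID = "HGNC")
    new_term$entity <- bel_entity(new_ns, new_term$entity$value)
  } else if (kind == "abundance_change") {
    new_term$abundance <- if (new_term$abundance == "p") "g" else "p"
    out$target_in_complex <- FALSE  # no level is affected; flags unused
    out$target_under_fn <- FALSE
  }
  s$subject <- replace_leaf(s$subject, target$term, new_term)
  s$object <- replace_leaf(s$object, target$term, new_term)
  out$text <- serialize_statement(s)
  out
}

#' Analytic expected counts from a perturbation log
#'
#' Sums, over the realized per-statement perturbation log, the per-level
#' TP/FP/FN deltas of the documented level-semantics table (e.g. a
#' relation flip removes relation- and statement-level credit but leaves
#' the secondary relation level intact). The result is what
#' [evaluate_corpus()] must report on the perturbed corpus.
#'
#' @param log The `log` tibble from [perturb()].
#' @return A tibble with columns `level`, `tp`, `fp`, `fn` (six cascade
#'   levels), consistent with the conservation law tp + fn = gold
#'   fragments per level.
#' @export
expected_counts <- function(log) {
  stopifnot(all(c("evidence_id", "error_kind", "n_terms", "n_functions")
                %in% names(log)))
  gold <- c(Term = sum(log$n_terms),
            Function = sum(log$n_functions),
            `Function-Secondary` = sum(log$n_functions),
            Relation = nrow(log),
            `Relation-Secondary` = nrow(log),
            Statement = nrow(log))
  deltas <- zero_deltas()
  for (i in seq_len(nrow(log))) {
    deltas <- deltas + error_deltas(
      log$error_kind[[i]],
      n_terms = log$n_terms[[i]],
      n_functions = log$n_functions[[i]],
      target_in_complex = isTRUE(log$target_in_complex[[i]]),
      target_under_fn = isTRUE(log$target_under_fn[[i]]),
      added_duplicate_ftype = isTRUE(log$added_duplicate_ftype[[i]]))
  }
  fn <- deltas[c("term_fn", "fn_fn", "fsec_fn", "rel_fn", "relsec_fn",
                 "stmt_fn")]
  fp <- deltas[c("term_fp", "fn_fp", "fsec_fp", "rel_fp", "relsec_fp",
                 "stmt_fp")]
  tibble::tibble(level = BEL_LEVELS,
                 tp = as.integer(unname(gold - fn)),
                 fp = as.integer(unname(fp)),
                 fn = as.integer(unname(fn)))
}
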