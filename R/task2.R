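# Evidence-retrieval evaluation: systems return up to 10 ranked evidence
# sentences per BEL statement; each sentence is manually labelled fully
# supportive (the sentence alone carries all information needed to curate
# the statement), partially supportive (context sentences or background
# knowledge are needed) or not supportive. Scoring uses micro precision,
# mean average precision over the rankings, inter-annotator kappa, and the
# weighted combination of classifier probabilities used for ranking.

SUPPORT_LABELS <- c("fully", "partially", "not_supportive")

label_relevant <- function(labels, criterion = c("full", "partial")) {
  criterion <- match.arg(criterion)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), SUPPORT_LABELS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown support label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (criterion == "full") labels == "fully"
  else labels %in% c("fully", "partially")
}

as_ranked_evidence <- function(evidences) {
  stopifnot(is.data.frame(evidences))
  need <- c("statement_id", "label")
  missing <- setdiff(need, names(evidences))
  if (length(missing) > 0L) {
    stop(sprintf("evidence table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ev <- tibble::as_tibble(evidences)
  if ("rank" %in% names(ev)) {
    ev <- dplyr::arrange(ev, .data$statement_id, .data$rank)
  }
  ev
}

#' Micro precision of retrieved evidence sentences
#'
#' Counts every retrieved sentence across all statements: under the `full`
#' criterion only fully supportive sentences are true positives; under the
#' `partial` criterion fully supportive counts as partially supportive, so
#' both grades are true positives. Precision is tp/(tp+fp) over the pooled
#' counts (micro level).
#'
#' @param evidences A data frame of retrieved sentences with columns
#'   `statement_id`, `label` (one of `"fully"`, `"partially"`,
#'   `"not_supportive"`) and optionally `rank`.
#' @param criterion `"full"` or `"partial"`.
#' @return A one-row tibble with `criterion`, `tp`, `fp`, `precision`,
#'   `statements_with_hit` (statements with at least one sentence meeting
#'   the criterion) and `sentences_per_statement`.
#' @examples
#' ev <- tibble::tibble(statement_id = c("s1", "s1", "s2"),
#'                      rank = c(1, 2, 1),
#'                      label = c("fully", "not_supportive", "partially"))
#' micro_precision(ev, "partial")
#' @export
micro_precision <- function(evidences, criterion = c("full", "partial")) {
  criterion <- match.arg(criterion)
  ev <- as_ranked_evidence(evidences)
  if (nrow(ev) == 0L) {
    warning("empty submission: precision is 0", call. = FALSE)
    return(tibble::tibble(criterion = criterion, tp = 0L, fp = 0L,
                          precision = 0, statements_with_hit = 0L,
                          sentences_per_statement = NaN))
  }
  rel <- label_relevant(ev$label, criterion)
  tp <- sum(rel)
  fp <- sum(!rel)
  hits <- ev |>
    dplyr::group_by(.data$statement_id) |>
    dplyr::summarise(hit = any(label_relevant(.data$label, criterion)),
                     .groups = "drop")
  tibble::tibble(
    criterion = criterion,
    tp = tp, fp = fp,
    precision = tp / (tp + fp),
    statements_with_hit = sum(hits$hit),
    sentences_per_statement = nrow(ev) / dplyr::n_distinct(ev$statement_id))
}

#' Average precision of one ranked list
#'
#' AP is the mean of precision-at-k over the ranks k holding a relevant
#' item, normalized by the number of relevant items retrieved in the list;
#' 0 when the list holds no relevant item.
#'
#' @param ranked_labels Logical vector of relevance in rank order.
#' @return A fraction in \[0, 1\].
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE)) # (1 + 2/3) / 2
#' @export
average_precision <- function(ranked_labels) {
  rel <- as.logical(ranked_labels)
  if (length(rel) == 0L || !any(rel)) return(0)
  k <- which(rel)
  mean(cumsum(rel)[k] / k)
}

#' Mean average precision over a labelled submission
#'
#' The unweighted mean of per-statement [average_precision()] over all
#' statements in the gold set; statements for which the system retrieved
#' nothing relevant (or nothing at all) contribute an AP of 0. Supply
#' `statement_ids` to include gold statements absent from the submission
#' in the denominator.
#'
#' @inheritParams micro_precision
#' @param statement_ids Optional character vector of all gold statement
#'   ids; defaults to the ids present in `evidences`.
#' @return A fraction in \[0, 1\].
#' @export
mean_average_precision <- function(evidences,
                                   criterion = c("full", "partial"),
                                   statement_ids = NULL) {
  criterion <- match.arg(criterion)
  ev <- as_ranked_evidence(evidences)
  if (is.null(statement_ids)) statement_ids <- unique(ev$statement_id)
  if (length(statement_ids) == 0L) return(0)
  ap <- vapply(statement_ids, function(sid) {
    labels <- ev$label[ev$statement_id == sid]
    average_precision(label_relevant(labels, criterion))
  }, numeric(1))
  mean(ap)
}

#' Cohen's kappa for two annotators
#'
#' Chance-corrected inter-annotator agreement
#' kappa = (p_o - p_e) / (1 - p_e), where p_o is the observed agreement
#' fraction and p_e the chance agreement expected from the two annotators'
#' marginal label distributions. When p_e = 1 (both annotators constant on
#' the same label), kappa is reported as 1 since agreement is perfect.
#'
#' @param labels_a,labels_b Equal-length vectors of category labels.
#' @return A list with `kappa`, `agreement` (raw percent agreement as a
#'   fraction) and `table` (the confusion table).
#' @examples
#' cohen_kappa(c("y", "y", "n", "n"), c("y", "n", "y", "n"))$kappa # 0
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labels_a and labels_b must have the same length", call. = FALSE)
  }
  if (length(labels_a) == 0L) {
    stop("need at least one pair of labels", call. = FALSE)
  }
  cats <- union(unique(as.character(labels_a)), unique(as.character(labels_b)))
  a <- factor(as.character(labels_a), levels = cats)
  b <- factor(as.character(labels_b), levels = cats)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (p_e >= 1) {
    if (p_o >= 1) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  list(kappa = kappa, agreement = p_o, table = tab)
}

#' Combine classifier probabilities into a sentence ranking score
#'
#' The ranking score of a candidate evidence sentence is the weighted sum
#' of the probabilities produced by the entity-entity, function-entity and
#' relationship classifiers:
#' `score = w_ee * p_ee + w_fe * p_fe + w_r * p_r`, with default weights
#' 0.4, 0.5 and 0.1.
#'
#' @param probs A data frame with numeric columns `p_ee`, `p_fe`, `p_r`
#'   (each in \[0, 1\]), one row per candidate sentence.
#' @param weights Named numeric vector or list with `w_ee`, `w_fe`, `w_r`.
#' @return The input tibble with a `score` column added.
#' @examples
#' combine_ranking_score(tibble::tibble(p_ee = 0.5, p_fe = 0.5, p_r = 0.5))
#' @export
combine_ranking_score <- function(probs,
                                  weights = c(w_ee = 0.4, w_fe = 0.5,
                                              w_r = 0.1)) {
  stopifnot(all(c("p_ee", "p_fe", "p_r") %in% names(probs)))
  w <- as.list(weights)
  stopifnot(all(c("w_ee", "w_fe", "w_r") %in% names(w)))
  tibble::as_tibble(probs) |>
    dplyr::mutate(score = w$w_ee * .data$p_ee + w$w_fe * .data$p_fe +
                    w$w_r * .data$p_r)
}

#' Evaluate a ranked evidence-retrieval submission
#'
#' Full task-2 report: micro precision and MAP under both the full and the
#' partial support criterion, plus retrieval volume statistics.
#'
#' @inheritParams mean_average_precision
#' @return A `bel_retrieval` object with a per-criterion tibble in
#'   `$criteria`; `tidy()`, `glance()` and `autoplot()` methods apply.
#' @export
evaluate_retrieval <- function(evidences, statement_ids = NULL) {
  ev <- as_ranked_evidence(evidences)
  rows <- dplyr::bind_rows(lapply(c("full", "partial"), function(cr) {
    mp <- micro_precision(ev, cr)
    mp$map <- mean_average_precision(ev, cr, statement_ids = statement_ids)
    mp
  }))
  structure(list(criteria = rows,
                 n_sentences = nrow(ev),
                 n_statements = length(
                   if (is.null(statement_ids)) unique(ev$statement_id)
                   else statement_ids)),
            class = "bel_retrieval")
}

#' @export
print.bel_retrieval <- function(x, ...) {
  cat(sprintf("<bel_retrieval> %d sentences for %d statements\n",
              x$n_sentences, x$n_statements))
  for (k in seq_len(nrow(x$criteria))) {
    r <- x$criteria[k, ]
    cat(sprintf("  %-8s TP %4d  FP %4d  precision %s%%  MAP %s%%\n",
                r$criterion, r$tp, r$fp,
                sprintf("%.1f", round_half_up(100 * r$precision, 1)),
                sprintf("%.1f", round_half_up(100 * r$map, 1))))
  }
  invisible(x)
}
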