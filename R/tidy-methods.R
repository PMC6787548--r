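# broom-style accessors and plots for the two report types.

#' Tidy a cascade evaluation report
#'
#' @param x A `bel_evaluation` from [evaluate_corpus()].
#' @param ... Unused.
#' @return A tibble with one row per cascade level: `level`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f_score`.
#' @export
tidy.bel_evaluation <- function(x, ...) {
  x$levels
}

#' Summarize a cascade evaluation in one row
#'
#' @param x A `bel_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble with the statement-level scores, the term-level
#'   F-score, and the number of ignored invalid predictions.
#' @export
glance.bel_evaluation <- function(x, ...) {
  stmt <- x$levels[x$levels$level == "Statement", ]
  term <- x$levels[x$levels$level == "Term", ]
  tibble::tibble(
    statement_f = stmt$f_score, statement_precision = stmt$precision,
    statement_recall = stmt$recall, term_f = term$f_score,
    ignored_invalid = x$ignored_invalid)
}

#' Plot per-level precision, recall and F of a cascade evaluation
#'
#' Bar chart of the three micro-averaged scores at each cascade level, in
#' cascade order from Term to Statement.
#'
#' @param object A `bel_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bel_evaluation <- function(object, ...) {
  df <- object$levels |>
    tidyr::pivot_longer(c("f_score", "precision", "recall"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(
      level = factor(.data$level, levels = BEL_LEVELS),
      metric = factor(.data$metric,
                      levels = c("f_score", "precision", "recall"),
                      labels = c("F", "P", "R")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "micro-averaged score", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Tidy a retrieval evaluation report
#'
#' @param x A `bel_retrieval` from [evaluate_retrieval()].
#' @param ... Unused.
#' @return The per-criterion tibble (`criterion`, `tp`, `fp`, `precision`,
#'   `statements_with_hit`, `sentences_per_statement`, `map`).
#' @export
tidy.bel_retrieval <- function(x, ...) {
  x$criteria
}

#' Summarize a retrieval evaluation in one row
#'
#' @param x A `bel_retrieval`.
#' @param ... Unused.
#' @return A one-row tibble with precision and MAP under both criteria and
#'   the submission volume.
#' @export
glance.bel_retrieval <- function(x, ...) {
  full <- x$criteria[x$criteria$criterion == "full", ]
  part <- x$criteria[x$criteria$criterion == "partial", ]
  tibble::tibble(
    precision_full = full$precision, map_full = full$map,
    precision_partial = part$precision, map_partial = part$map,
    n_sentences = x$n_sentences, n_statements = x$n_statements)
}

#' Plot precision and MAP of a retrieval evaluation
#'
#' @param object A `bel_retrieval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bel_retrieval <- function(object, ...) {
  df <- object$criteria |>
    tidyr::pivot_longer(c("precision", "map"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric,
                                  levels = c("precision", "map"),
                                  labels = c("Precision", "MAP")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "support criterion", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
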