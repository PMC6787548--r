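# Namespace–abundance compatibility of the track's subset:
#   bp() only with GOBP, path() only with MESHD, a() only with CHEBI,
#   p()/g()/r() only with the gene namespaces (HGNC/MGI/EGID),
#   named complex() only with GOCC, tloc() locations only GOCC.
ABUNDANCE_NAMESPACES <- list(
  p = GENE_NAMESPACES, g = GENE_NAMESPACES, r = GENE_NAMESPACES,
  a = "CHEBI", bp = "GOBP", path = "MESHD", complex = "GOCC"
)

node_pos <- function(node) {
  p <- node$pos
  if (is.null(p) || is.na(p)) 1L else as.integer(p)
}

check_node <- function(node, errors) {
  if (is_bel_term(node)) {
    if (!is.null(node$members)) {
      for (m in node$members) errors <- check_node(m, errors)
      return(errors)
    }
    allowed <- ABUNDANCE_NAMESPACES[[node$abundance]]
    if (!node$entity$namespace %in% allowed) {
      errors <- add_error(errors, node_pos(node), sprintf(
        "abundance %s() is not compatible with namespace %s (allowed: %s)",
        node$abundance, node$entity$namespace, paste(allowed, collapse = ", ")))
    }
    return(errors)
  }
  # function node
  if (is_modifier_fn(node)) {
    base <- node$inner
    while (is_modifier_fn(base)) base <- base$inner
    if (!(is_bel_term(base) && base$abundance %in% c("p", "g", "r"))) {
      errors <- add_error(errors, node_pos(node), sprintf(
        "%s is only valid on a gene-product abundance term",
        sub("_.*$", "()", paste0(node$ftype, "_"))))
    }
  }
  if (node$ftype == "tloc") {
    for (loc in list(node$from_loc, node$to_loc)) {
      if (!is.null(loc) && loc$namespace != "GOCC") {
        errors <- add_error(errors, node_pos(node), sprintf(
          "tloc() locations must be GOCC, found %s", loc$namespace))
      }
    }
  }
  check_node(node$inner, errors)
}

add_error <- function(errors, position, message) {
  dplyr::bind_rows(errors,
                   tibble::tibble(position = as.integer(position),
                                  message = message))
}

empty_errors <- function() {
  tibble::tibble(position = integer(), message = character())
}

#' Validate a BEL statement string
#'
#' Checks a candidate statement line for formal correctness: it must parse
#' under the restricted grammar and every term must respect the
#' namespace–abundance compatibility rules of the track's subset. Invalid
#' statements are reported, not raised: each violation yields one error
#' record with a character position and a message, mirroring the behaviour
#' of the track's online validator. [evaluate_corpus()] uses this to ignore
#' invalid predictions.
#'
#' @param text A candidate statement line.
#' @return A `bel_validation` list with `valid` (logical) and `errors`
#'   (a tibble with columns `position`, `message`); `valid` is `TRUE` iff
#'   `errors` has no rows. When parsing succeeded the parsed statement is
#'   attached as `$statement`.
#' @examples
#' validate_statement("p(HGNC:IL1B) increases p(HGNC:ATF2, pmod(P))")$valid
#' validate_statement("bp(HGNC:TNF) increases p(HGNC:ATF2)")$errors
#' @export
validate_statement <- function(text) {
  errors <- empty_errors()
  statement <- NULL
  parsed <- tryCatch(parse_statement(text), bel_parse_error = function(e) e)
  if (inherits(parsed, "bel_parse_error")) {
    errors <- add_error(errors, parsed$position, parsed$bel_message)
  } else {
    statement <- parsed
    errors <- check_node(statement$subject, errors)
    errors <- check_node(statement$object, errors)
  }
  structure(list(valid = nrow(errors) == 0L, errors = errors,
                 statement = statement),
            class = "bel_validation")
}

#' @export
print.bel_validation <- function(x, ...) {
  if (x$valid) {
    cat("<bel_validation> valid\n")
  } else {
    cat("<bel_validation> invalid:\n")
    for (k in seq_len(nrow(x$errors))) {
      cat(sprintf("  [pos %d] %s\n", x$errors$position[k], x$errors$message[k]))
    }
  }
  invisible(x)
}
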