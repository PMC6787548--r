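# Cascade decomposition: a statement is cut into the fragment multiset
# evaluated at each level — leaf terms (complex members individually plus
# the complex term itself), function fragments paired with their inner
# term, bare function types for the secondary function level, a
# function-stripped relation triple, and the full statement.

#' Strip function wrappers from a term or function node
#'
#' Returns the leaf term(s) under any chain of function wrappers. A
#' composed complex yields each member's leaf terms plus the complex term
#' itself, so that complex members are individually addressable during
#' matching.
#'
#' @param node A `bel_term` or `bel_fn`.
#' @return A list of `bel_term` objects.
#' @examples
#' strip_functions(parse_term("act(p(HGNC:EDNRA))"))
#' @export
strip_functions <- function(node) {
  if (is_bel_fn(node)) return(strip_functions(node$inner))
  if (!is.null(node$members)) {
    leaves <- unlist(lapply(node$members, strip_functions), recursive = FALSE)
    return(c(leaves, list(node)))
  }
  list(node)
}

collect_function_nodes <- function(node) {
  if (is_bel_fn(node)) {
    return(c(list(node), collect_function_nodes(node$inner)))
  }
  if (!is.null(node$members)) {
    return(unlist(lapply(node$members, collect_function_nodes),
                  recursive = FALSE))
  }
  list()
}

#' Decompose a statement into its cascade fragments
#'
#' Cuts a parsed statement into the fragments scored at each evaluation
#' level: `terms` holds every leaf term of subject and object (complex
#' members individually plus the complex term), `functions` pairs each
#' function node with its inner term, `secondary_functions` lists one
#' function type per function node, `relation` is the function-stripped
#' (subject terms, relation, object terms) triple, and `statement` is the
#' statement itself.
#'
#' @param s A `bel_statement`.
#' @return A `bel_fragments` list with slots `terms`, `functions`,
#'   `secondary_functions`, `relation`, `statement`.
#' @examples
#' fb <- fragment_statement(
#'   parse_statement("p(HGNC:IL1B) increases p(HGNC:ATF2, pmod(P))"))
#' length(fb$terms)
#' fb$secondary_functions
#' @export
fragment_statement <- function(s) {
  stopifnot(inherits(s, "bel_statement"))
  subject_terms <- strip_functions(s$subject)
  object_terms <- strip_functions(s$object)
  fn_nodes <- c(collect_function_nodes(s$subject),
                collect_function_nodes(s$object))
  functions <- lapply(fn_nodes, as_function_fragment)
  structure(list(
    terms = c(subject_terms, object_terms),
    functions = functions,
    secondary_functions = vapply(fn_nodes, fragment_ftype, character(1)),
    relation = list(subject_terms = subject_terms,
                    relation = s$relation,
                    object_terms = object_terms),
    statement = s
  ), class = "bel_fragments")
}

# Canonical identity keys used for within-evidence deduplication (exact,
# not equivalence-based).
term_frag_key <- function(t) serialize_node(t)
fn_frag_key <- function(f) paste0(f$ftype, "|", serialize_node(f$node))
relation_frag_key <- function(r) {
  paste0(paste(sort(vapply(r$subject_terms, serialize_node, character(1))),
               collapse = "+"),
         " ", r$relation, " ",
         paste(sort(vapply(r$object_terms, serialize_node, character(1))),
               collapse = "+"))
}
statement_frag_key <- function(s) serialize_statement(s)
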