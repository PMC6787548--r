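# Canonical serialization: short function names, no space before "(", one
# space after commas, straight double quotes only where the value requires
# them. parse(serialize(x)) reproduces x, and serialize is idempotent
# through a parse round-trip.

needs_quotes <- function(value) grepl("[^A-Za-z0-9_-]", value)

serialize_entity <- function(e) {
  value <- if (needs_quotes(e$value)) paste0('"', e$value, '"') else e$value
  paste0(e$namespace, ":", value)
}

MODIFIER_FTYPES <- c("sub", "trunc")

is_modifier_fn <- function(node) {
  is_bel_fn(node) &&
    (startsWith(node$ftype, "pmod_") || node$ftype %in% MODIFIER_FTYPES)
}

serialize_modifier <- function(node) {
  if (startsWith(node$ftype, "pmod_")) {
    args <- c(sub("^pmod_", "", node$ftype), node$extra_args)
    paste0("pmod(", paste(args, collapse = ", "), ")")
  } else {
    paste0(node$ftype, "(", paste(node$extra_args, collapse = ", "), ")")
  }
}

serialize_node <- function(node) {
  if (is_bel_term(node)) {
    if (!is.null(node$members)) {
      return(paste0("complex(",
                    paste(vapply(node$members, serialize_node, character(1)),
                          collapse = ", "),
                    ")"))
    }
    return(paste0(node$abundance, "(", serialize_entity(node$entity), ")"))
  }
  if (is_modifier_fn(node)) {
    # modification chains print inside the base term's parentheses,
    # innermost modifier first: p(HGNC:ATF2, pmod(P))
    mods <- character()
    base <- node
    while (is_modifier_fn(base)) {
      mods <- c(serialize_modifier(base), mods)
      base <- base$inner
    }
    base_txt <- serialize_node(base)
    return(paste0(sub("\\)$", "", base_txt), ", ",
                  paste(mods, collapse = ", "), ")"))
  }
  if (node$ftype == "act") {
    name <- if (is.null(node$subtype)) "act" else node$subtype
    return(paste0(name, "(", serialize_node(node$inner), ")"))
  }
  if (node$ftype == "tloc") {
    parts <- serialize_node(node$inner)
    if (!is.null(node$from_loc)) parts <- c(parts, serialize_entity(node$from_loc))
    if (!is.null(node$to_loc)) parts <- c(parts, serialize_entity(node$to_loc))
    return(paste0("tloc(", paste(parts, collapse = ", "), ")"))
  }
  paste0(node$ftype, "(", serialize_node(node$inner), ")")
}

#' Serialize a BEL statement to its canonical spelling
#'
#' Produces the single canonical surface form of a parsed statement: short
#' function names, no whitespace before `(`, one space after each comma, and
#' straight double quotes only around values that need them. Re-parsing the
#' output reproduces the same tree.
#'
#' @param s A `bel_statement` from [parse_statement()].
#' @return A single string.
#' @examples
#' serialize_statement(parse_statement("p (HGNC:IL1B) increases p (HGNC:ATF2, pmod(P))"))
#' @export
serialize_statement <- function(s) {
  stopifnot(inherits(s, "bel_statement"))
  paste(serialize_node(s$subject), s$relation, serialize_node(s$object))
}

#' Serialize a BEL term or function node
#'
#' @param node A `bel_term` or `bel_fn`.
#' @return A single string in canonical spelling.
#' @export
serialize_term <- function(node) {
  stopifnot(is_bel_term(node) || is_bel_fn(node))
  serialize_node(node)
}
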