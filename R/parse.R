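# The seven namespaces admitted by the track's restricted BEL subset.
BEL_NAMESPACES <- c("HGNC", "MGI", "EGID", "CHEBI", "MESHD", "GOBP", "GOCC")
GENE_NAMESPACES <- c("HGNC", "MGI", "EGID")

# Short and BEL-1.0 long spellings of the abundance functions, mapped to the
# canonical short form used on output.
BEL_ABUNDANCES <- c(
  p = "p", proteinAbundance = "p",
  a = "a", abundance = "a",
  bp = "bp", biologicalProcess = "bp",
  path = "path", pathology = "path",
  g = "g", geneAbundance = "g",
  r = "r", rnaAbundance = "r",
  complex = "complex", complexAbundance = "complex"
)

# Activity functions: every subtype collapses to ftype "act" for evaluation;
# the parsed subtype (short form) is retained on the node and on output.
BEL_ACTIVITIES <- c(
  act = "act", molecularActivity = "act",
  cat = "cat", catalyticActivity = "cat",
  kin = "kin", kinaseActivity = "kin",
  phos = "phos", phosphataseActivity = "phos",
  pep = "pep", peptidaseActivity = "pep",
  ribo = "ribo", ribosylationActivity = "ribo",
  tscript = "tscript", transcriptionalActivity = "tscript",
  tport = "tport", transportActivity = "tport",
  gtp = "gtp", gtpBoundActivity = "gtp",
  chap = "chap", chaperoneActivity = "chap"
)

BEL_WRAPPERS <- c(tloc = "tloc", translocation = "tloc",
                  deg = "deg", degradation = "deg")

# Term-internal modification functions, e.g. p(HGNC:ATF2, pmod(P)).
BEL_MODIFIERS <- c(pmod = "pmod", proteinModification = "pmod",
                   sub = "sub", substitution = "sub",
                   trunc = "trunc", truncation = "trunc")

bel_entity <- function(namespace, value, pos = NA_integer_) {
  structure(list(namespace = namespace, value = value, pos = pos),
            class = "bel_entity")
}

bel_term <- function(abundance, entity = NULL, members = NULL,
                     pos = NA_integer_) {
  structure(list(abundance = abundance, entity = entity, members = members,
                 pos = pos),
            class = "bel_term")
}

bel_fn <- function(ftype, inner, subtype = NULL, from_loc = NULL,
                   to_loc = NULL, extra_args = character(),
                   pos = NA_integer_) {
  structure(list(ftype = ftype, inner = inner, subtype = subtype,
                 from_loc = from_loc, to_loc = to_loc,
                 extra_args = extra_args, pos = pos),
            class = "bel_fn")
}

bel_statement <- function(subject, relation, object, evidence_id = "",
                          raw_text = "") {
  structure(list(subject = subject, relation = relation, object = object,
                 evidence_id = evidence_id, raw_text = raw_text),
            class = "bel_statement")
}

is_bel_term <- function(x) inherits(x, "bel_term")
is_bel_fn <- function(x) inherits(x, "bel_fn")

bel_parse_error <- function(message, position) {
  stop(errorCondition(
    sprintf("BEL syntax error at position %d: %s", position, message),
    position = position, bel_message = message,
    class = c("bel_parse_error", "error")
  ))
}

# ---- tokenizer ---------------------------------------------------------

# Token types: word, quoted, lparen, rparen, comma, colon, arrow.
# Unquoted values are limited to [A-Za-z0-9_-]; "-" is treated as part of a
# word only when followed by another word character, so the relation arrows
# "->" and "-|" tokenize unambiguously.
bel_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- vector("list", n)
  nt <- 0L
  i <- 1L
  word_char <- function(ch) grepl("[A-Za-z0-9_]", ch)
  open_quotes <- c("\"", "“", "”")
  close_quotes <- c("\"", "“", "”")
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    nt <- nt + 1L
    if (ch == "(") { toks[[nt]] <- list(type = "lparen", value = "(", pos = i); i <- i + 1L; next }
    if (ch == ")") { toks[[nt]] <- list(type = "rparen", value = ")", pos = i); i <- i + 1L; next }
    if (ch == ",") { toks[[nt]] <- list(type = "comma", value = ",", pos = i); i <- i + 1L; next }
    if (ch == ":") { toks[[nt]] <- list(type = "colon", value = ":", pos = i); i <- i + 1L; next }
    if (ch %in% c("-", "=") && i < n && chars[i + 1L] %in% c(">", "|")) {
      toks[[nt]] <- list(type = "arrow", value = paste0(ch, chars[i + 1L]), pos = i)
      i <- i + 2L
      next
    }
    if (ch %in% open_quotes) {
      j <- i + 1L
      while (j <= n && !(chars[j] %in% close_quotes)) j <- j + 1L
      if (j > n) bel_parse_error("unterminated quoted value", i)
      toks[[nt]] <- list(type = "quoted",
                         value = paste(chars[seq(i + 1L, length.out = j - i - 1L)], collapse = ""),
                         pos = i)
      i <- j + 1L
      next
    }
    if (word_char(ch)) {
      j <- i
      while (j < n && (word_char(chars[j + 1L]) ||
                       (chars[j + 1L] == "-" && j + 2L <= n && word_char(chars[j + 2L])))) {
        j <- j + 1L
      }
      toks[[nt]] <- list(type = "word",
                         value = paste(chars[i:j], collapse = ""), pos = i)
      i <- j + 1L
      next
    }
    bel_parse_error(sprintf("unexpected character '%s'", ch), i)
  }
  toks[seq_len(nt)]
}

# ---- recursive-descent parser ------------------------------------------

new_cursor <- function(toks, text) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$i <- 1L
  env$end_pos <- nchar(text) + 1L
  env
}

peek <- function(cur) if (cur$i <= length(cur$toks)) cur$toks[[cur$i]] else NULL

advance <- function(cur) {
  tok <- peek(cur)
  cur$i <- cur$i + 1L
  tok
}

cur_pos <- function(cur) {
  tok <- peek(cur)
  if (is.null(tok)) cur$end_pos else tok$pos
}

expect_tok <- function(cur, type, what) {
  tok <- peek(cur)
  if (is.null(tok) || tok$type != type) {
    bel_parse_error(sprintf("expected %s", what), cur_pos(cur))
  }
  advance(cur)
}

parse_entity_tokens <- function(cur) {
  ns_tok <- peek(cur)
  if (is.null(ns_tok) || ns_tok$type != "word") {
    bel_parse_error("expected a namespace prefix", cur_pos(cur))
  }
  advance(cur)
  ns <- toupper(ns_tok$value)
  if (!ns %in% BEL_NAMESPACES) {
    bel_parse_error(sprintf("unknown namespace '%s'", ns_tok$value), ns_tok$pos)
  }
  expect_tok(cur, "colon", "':' after namespace prefix")
  val_tok <- peek(cur)
  if (is.null(val_tok) || !val_tok$type %in% c("word", "quoted")) {
    bel_parse_error("expected an entity value after ':'", cur_pos(cur))
  }
  advance(cur)
  if (!nzchar(val_tok$value)) {
    bel_parse_error("empty entity value", val_tok$pos)
  }
  bel_entity(ns, val_tok$value, pos = ns_tok$pos)
}

# An entity reference starts word ':' — used to disambiguate complex(NS:v)
# from complex(p(...), ...).
at_entity <- function(cur) {
  tok <- peek(cur)
  nxt <- if (cur$i + 1L <= length(cur$toks)) cur$toks[[cur$i + 1L]] else NULL
  !is.null(tok) && tok$type == "word" && !is.null(nxt) && nxt$type == "colon"
}

parse_modifier <- function(cur, name_tok, inner) {
  fname <- BEL_MODIFIERS[[name_tok$value]]
  expect_tok(cur, "lparen", sprintf("'(' after '%s'", name_tok$value))
  args <- character()
  repeat {
    tok <- peek(cur)
    if (is.null(tok)) bel_parse_error("unbalanced parentheses", cur_pos(cur))
    if (tok$type == "rparen") break
    if (!tok$type %in% c("word", "quoted")) {
      bel_parse_error(sprintf("unexpected token in %s() arguments", fname), tok$pos)
    }
    advance(cur)
    args <- c(args, tok$value)
    tok <- peek(cur)
    if (!is.null(tok) && tok$type == "comma") advance(cur)
  }
  expect_tok(cur, "rparen", "')'")
  if (fname == "pmod") {
    if (length(args) == 0L) {
      bel_parse_error("pmod() requires a modification type", name_tok$pos)
    }
    bel_fn(paste0("pmod_", args[[1L]]), inner,
           extra_args = args[-1L], pos = name_tok$pos)
  } else {
    bel_fn(fname, inner, extra_args = args, pos = name_tok$pos)
  }
}

parse_node <- function(cur) {
  name_tok <- peek(cur)
  if (is.null(name_tok) || name_tok$type != "word") {
    bel_parse_error("expected a BEL term or function", cur_pos(cur))
  }
  fname <- name_tok$value
  if (fname %in% names(BEL_ABUNDANCES)) {
    advance(cur)
    return(parse_abundance(cur, name_tok, BEL_ABUNDANCES[[fname]]))
  }
  if (fname %in% names(BEL_ACTIVITIES)) {
    advance(cur)
    expect_tok(cur, "lparen", sprintf("'(' after '%s'", fname))
    # entity shorthand cat(HGNC:XIAP) is accepted as cat(p(HGNC:XIAP))
    inner <- if (at_entity(cur)) {
      e <- parse_entity_tokens(cur)
      bel_term("p", entity = e, pos = e$pos)
    } else {
      parse_node(cur)
    }
    expect_tok(cur, "rparen", "')'")
    subtype <- BEL_ACTIVITIES[[fname]]
    return(bel_fn("act", inner,
                  subtype = if (subtype == "act") NULL else subtype,
                  pos = name_tok$pos))
  }
  if (fname %in% names(BEL_WRAPPERS)) {
    advance(cur)
    canon <- BEL_WRAPPERS[[fname]]
    expect_tok(cur, "lparen", sprintf("'(' after '%s'", fname))
    inner <- parse_node(cur)
    from_loc <- NULL
    to_loc <- NULL
    if (canon == "tloc") {
      if (!is.null(peek(cur)) && peek(cur)$type == "comma") {
        advance(cur)
        from_loc <- parse_entity_tokens(cur)
        if (!is.null(peek(cur)) && peek(cur)$type == "comma") {
          advance(cur)
          to_loc <- parse_entity_tokens(cur)
        }
      }
    }
    expect_tok(cur, "rparen", "')'")
    return(bel_fn(canon, inner, from_loc = from_loc, to_loc = to_loc,
                  pos = name_tok$pos))
  }
  if (fname %in% names(BEL_MODIFIERS)) {
    bel_parse_error(
      sprintf("'%s' is only allowed inside an abundance term", fname),
      name_tok$pos)
  }
  bel_parse_error(sprintf("unknown function '%s'", fname), name_tok$pos)
}

parse_abundance <- function(cur, name_tok, abundance) {
  expect_tok(cur, "lparen", sprintf("'(' after '%s'", name_tok$value))
  if (abundance == "complex") {
    node <- parse_complex_body(cur, name_tok)
    expect_tok(cur, "rparen", "')'")
    return(node)
  }
  entity <- parse_entity_tokens(cur)
  node <- bel_term(abundance, entity = entity, pos = name_tok$pos)
  # trailing arguments must be modification functions: p(HGNC:ATF2, pmod(P))
  while (!is.null(peek(cur)) && peek(cur)$type == "comma") {
    advance(cur)
    mod_tok <- peek(cur)
    if (is.null(mod_tok) || mod_tok$type != "word" ||
        !mod_tok$value %in% names(BEL_MODIFIERS)) {
      bel_parse_error(
        sprintf("expected a modification function inside %s()", abundance),
        cur_pos(cur))
    }
    advance(cur)
    node <- parse_modifier(cur, mod_tok, node)
  }
  expect_tok(cur, "rparen", "')'")
  node
}

parse_complex_body <- function(cur, name_tok) {
  if (at_entity(cur)) {
    entity <- parse_entity_tokens(cur)
    return(bel_term("complex", entity = entity, pos = name_tok$pos))
  }
  members <- list()
  repeat {
    members[[length(members) + 1L]] <- parse_node(cur)
    tok <- peek(cur)
    if (is.null(tok)) bel_parse_error("unbalanced parentheses", cur_pos(cur))
    if (tok$type != "comma") break
    advance(cur)
  }
  if (length(members) < 2L) {
    bel_parse_error("complex() needs at least two member terms or a namespace entity",
                    name_tok$pos)
  }
  bel_term("complex", members = members, pos = name_tok$pos)
}

parse_relation_tokens <- function(cur) {
  tok <- peek(cur)
  if (is.null(tok)) bel_parse_error("missing relation", cur_pos(cur))
  if (tok$type == "arrow") {
    advance(cur)
    return(normalize_relation(tok$value))
  }
  if (tok$type == "word") {
    if (tolower(tok$value) == "directly") {
      advance(cur)
      nxt <- peek(cur)
      if (is.null(nxt) || nxt$type != "word") {
        bel_parse_error("incomplete relation after 'directly'", cur_pos(cur))
      }
      advance(cur)
      return(normalize_relation(paste(tok$value, nxt$value)))
    }
    if (tolower(tok$value) %in% c("increases", "decreases")) {
      advance(cur)
      return(normalize_relation(tok$value))
    }
  }
  bel_parse_error(sprintf("expected a relation, found '%s'", tok$value), tok$pos)
}

#' Normalize a BEL relation token
#'
#' Maps the track's relation spellings onto the two canonical causal
#' relationship types. `"directly increases"` and the arrow symbols `->` and
#' `=>` normalize to `"increases"`; `"directly decreases"`, `-|` and `=|`
#' normalize to `"decreases"`.
#'
#' @param token A relation word (possibly with a `"directly"` qualifier) or a
#'   BEL arrow symbol.
#' @return `"increases"` or `"decreases"`.
#' @examples
#' normalize_relation("directly increases")
#' normalize_relation("-|")
#' @export
normalize_relation <- function(token) {
  key <- tolower(stringr::str_squish(token))
  out <- switch(key,
    "increases" = , "directly increases" = , "->" = , "=>" = "increases",
    "decreases" = , "directly decreases" = , "-|" = , "=|" = "decreases",
    NULL)
  if (is.null(out)) {
    bel_parse_error(sprintf("unknown relation '%s'", token), 1L)
  }
  out
}

#' Parse a BEL statement
#'
#' Parses one statement of the track's restricted BEL subset into a tree of
#' terms and function nodes. Both short and long function names are accepted
#' (`p`/`proteinAbundance`, `act`/`molecularActivity`, ...), whitespace is
#' tolerated between a function name and its opening parenthesis, namespace
#' prefixes are case-insensitive, and both straight and typographic double
#' quotes delimit values containing special characters. Activity subtypes
#' such as `catalyticActivity` parse to `act` nodes that retain the subtype.
#'
#' @param text A single candidate statement line.
#' @param evidence_id Optional identifier of the evidence sentence the
#'   statement was extracted from.
#' @return A `bel_statement` with fields `subject`, `relation` (`"increases"`
#'   or `"decreases"`), `object`, `evidence_id` and `raw_text`.
#' @examples
#' s <- parse_statement("p (HGNC:IL1B) increases p (HGNC:ATF2, pmod(P))")
#' serialize_statement(s)
#' @seealso [serialize_statement()], [validate_statement()], [parse_term()]
#' @export
parse_statement <- function(text, evidence_id = "") {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    bel_parse_error("empty input", 1L)
  }
  cur <- new_cursor(bel_tokenize(text), text)
  subject <- parse_node(cur)
  relation <- parse_relation_tokens(cur)
  object <- parse_node(cur)
  tok <- peek(cur)
  if (!is.null(tok)) {
    bel_parse_error(sprintf("unexpected trailing input '%s'", tok$value), tok$pos)
  }
  bel_statement(subject, relation, object,
                evidence_id = evidence_id, raw_text = text)
}

#' Parse a single BEL term or function expression
#'
#' Entry point for the sub-grammar used in fragment files: parses one term
#' (e.g. `path(MESHD:Colitis)`) or one function expression (e.g.
#' `act(p(HGNC:EDNRA))`) with the same tree construction as
#' [parse_statement()].
#'
#' @param text One term or function expression.
#' @return A `bel_term` or `bel_fn` node.
#' @examples
#' parse_term("complex(p(HGNC:JUN), p(HGNC:FOS))")
#' @export
parse_term <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    bel_parse_error("empty input", 1L)
  }
  cur <- new_cursor(bel_tokenize(text), text)
  node <- parse_node(cur)
  tok <- peek(cur)
  if (!is.null(tok)) {
    bel_parse_error(sprintf("unexpected trailing input '%s'", tok$value), tok$pos)
  }
  node
}

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement> ", serialize_statement(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.bel_term <- function(x, ...) {
  cat("<bel_term> ", serialize_node(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.bel_fn <- function(x, ...) {
  cat("<bel_fn> ", serialize_node(x), "\n", sep = "")
  invisible(x)
}
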