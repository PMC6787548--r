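# Matching simplifications used at every cascade level: gene identifiers
# from HGNC, EntrezGene (EGID) or mouse-ortholog MGI are interchangeable via
# an equivalence map, any gene-product abundance (p/g/r) is accepted, a
# composed complex matches when at least one member matches, tloc() matches
# on its inner term (locations optional), and pmod matches on the
# modification type alone.

# Case policy: namespaces are canonicalized to upper case at parse time;
# purely numeric identifiers compare case-sensitively (trivially), all other
# values compare case-insensitively.
entity_key <- function(e) {
  value <- if (grepl("^[0-9]+$", e$value)) e$value else toupper(e$value)
  paste0(e$namespace, ":", value)
}

new_equivalence_map <- function(group_ids = character()) {
  structure(list(group_ids = group_ids), class = "bel_equivalence_map")
}

#' Load a cross-namespace gene equivalence table
#'
#' Reads a TSV with header columns `HGNC`, `EGID` and `MGI` (any order);
#' each row lists identifiers of one gene across the three namespaces,
#' blank cells allowed. Rows sharing an identifier are merged transitively
#' into one group, so the resulting groups are disjoint.
#'
#' @param path Path to the tab-separated table. An empty file yields an
#'   empty map.
#' @return A `bel_equivalence_map` used by the `*_equivalent()` predicates
#'   and by [evaluate_corpus()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("HGNC\tEGID\tMGI", "IL1B\t3553\tIl1b"), tf)
#' m <- load_equivalence_map(tf)
#' entities_equivalent(parse_term("p(HGNC:IL1B)")$entity,
#'                     parse_term("p(MGI:Il1b)")$entity, m)
#' @export
load_equivalence_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(new_equivalence_map())
  header <- toupper(trimws(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]))
  wanted <- c("HGNC", "EGID", "MGI")
  if (!setequal(header, wanted) || length(header) != 3L) {
    stop("line 1: expected header columns HGNC, EGID, MGI", call. = FALSE)
  }
  col_ns <- header
  group_ids <- character()
  groups <- list()
  next_gid <- 1L
  for (k in seq_along(lines)[-1L]) {
    cells <- trimws(strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]])
    if (length(cells) > 3L) {
      stop(sprintf("line %d: expected 3 columns, found %d", k, length(cells)),
           call. = FALSE)
    }
    cells <- c(cells, rep("", 3L - length(cells)))
    keys <- character()
    for (j in seq_len(3L)) {
      if (nzchar(cells[[j]])) {
        keys <- c(keys, entity_key(bel_entity(col_ns[[j]], cells[[j]])))
      }
    }
    if (length(keys) == 0L) next
    hit_gids <- unique(unname(group_ids[intersect(keys, names(group_ids))]))
    if (length(hit_gids) == 0L) {
      gid <- as.character(next_gid)
      next_gid <- next_gid + 1L
      groups[[gid]] <- character()
    } else {
      gid <- hit_gids[[1L]]
      # transitive merge of any other groups this row touches
      for (other in setdiff(hit_gids, gid)) {
        members <- groups[[other]]
        groups[[gid]] <- c(groups[[gid]], members)
        group_ids[members] <- gid
        groups[[other]] <- NULL
      }
    }
    fresh <- setdiff(keys, names(group_ids))
    group_ids[fresh] <- gid
    groups[[gid]] <- unique(c(groups[[gid]], keys))
  }
  new_equivalence_map(group_ids)
}

#' Test whether two namespaced entities are equivalent
#'
#' Two entities are equivalent when their canonical keys are equal, or when
#' both are gene identifiers (HGNC/EGID/MGI) that belong to the same group
#' of the equivalence map. Non-gene namespaces require exact namespace and
#' value equality. Without a map, matching degenerates to exact identity.
#'
#' @param a,b `bel_entity` objects.
#' @param map A `bel_equivalence_map` from [load_equivalence_map()], or
#'   `NULL` for exact matching.
#' @return Logical scalar.
#' @export
entities_equivalent <- function(a, b, map = NULL) {
  ka <- entity_key(a)
  kb <- entity_key(b)
  if (ka == kb) return(TRUE)
  if (is.null(map)) return(FALSE)
  if (!(a$namespace %in% GENE_NAMESPACES && b$namespace %in% GENE_NAMESPACES)) {
    return(FALSE)
  }
  ga <- map$group_ids[ka]
  gb <- map$group_ids[kb]
  !is.na(ga) && !is.na(gb) && ga == gb
}

is_gene_term <- function(t) {
  is.null(t$members) && t$abundance %in% c("p", "g", "r") &&
    t$entity$namespace %in% GENE_NAMESPACES
}

#' Test whether two BEL terms are equivalent under the track simplifications
#'
#' For gene-product terms the abundances `p()`, `g()` and `r()` are
#' interchangeable and only entity equivalence is required; for all other
#' namespaces both the abundance and the entity must match. Two composed
#' complexes are equivalent when at least one pair of members is equivalent;
#' two named complexes compare on their entity.
#'
#' @param a,b `bel_term` objects.
#' @inheritParams entities_equivalent
#' @return Logical scalar.
#' @examples
#' terms_equivalent(parse_term("g(HGNC:IL1B)"), parse_term("p(HGNC:IL1B)"))
#' @export
terms_equivalent <- function(a, b, map = NULL) {
  stopifnot(is_bel_term(a), is_bel_term(b))
  a_complex <- a$abundance == "complex"
  b_complex <- b$abundance == "complex"
  if (a_complex != b_complex) return(FALSE)
  if (a_complex) {
    if (is.null(a$members) && is.null(b$members)) {
      return(entities_equivalent(a$entity, b$entity, map))
    }
    if (is.null(a$members) || is.null(b$members)) return(FALSE)
    for (ma in a$members) {
      for (mb in b$members) {
        la <- strip_functions(ma)
        lb <- strip_functions(mb)
        for (ta in la) for (tb in lb) {
          if (terms_equivalent(ta, tb, map)) return(TRUE)
        }
      }
    }
    return(FALSE)
  }
  if (is_gene_term(a) && is_gene_term(b)) {
    return(entities_equivalent(a$entity, b$entity, map))
  }
  a$abundance == b$abundance && entities_equivalent(a$entity, b$entity, map)
}

any_pair_equivalent <- function(terms_a, terms_b, map = NULL) {
  for (ta in terms_a) for (tb in terms_b) {
    if (terms_equivalent(ta, tb, map)) return(TRUE)
  }
  FALSE
}

#' Test whether two function fragments are equivalent
#'
#' A function is only accepted together with its argument: the function
#' types must agree (activity subtypes all collapse to `act`; `pmod`
#' compares the modification type only) and the inner terms must be
#' equivalent. For `tloc()` the locations are ignored by default; with
#' `strict_tloc = TRUE` both GOCC locations must also match. A function on a
#' composed complex is accepted when at least one complex member matches.
#'
#' @param a,b Function fragments as returned in the `functions` slot of
#'   [fragment_statement()], or `bel_fn` nodes.
#' @inheritParams entities_equivalent
#' @param strict_tloc Require both tloc() locations to match.
#' @return Logical scalar.
#' @export
functions_equivalent <- function(a, b, map = NULL, strict_tloc = FALSE) {
  a <- as_function_fragment(a)
  b <- as_function_fragment(b)
  if (a$ftype != b$ftype) return(FALSE)
  if (strict_tloc && a$ftype == "tloc") {
    if (!locations_match(a$node, b$node, map)) return(FALSE)
  }
  any_pair_equivalent(a$inner_terms, b$inner_terms, map)
}

locations_match <- function(na, nb, map) {
  one <- function(la, lb) {
    if (is.null(la) && is.null(lb)) return(TRUE)
    if (is.null(la) || is.null(lb)) return(FALSE)
    entities_equivalent(la, lb, map)
  }
  one(na$from_loc, nb$from_loc) && one(na$to_loc, nb$to_loc)
}

as_function_fragment <- function(x) {
  if (is_bel_fn(x)) {
    return(list(ftype = fragment_ftype(x), node = x,
                inner_terms = strip_functions(x$inner)))
  }
  x
}

# pmod keeps its modification type in the fragment type; activity subtypes
# collapse to plain act.
fragment_ftype <- function(node) node$ftype

#' Count matching units between two relation fragments
#'
#' A relation fragment is a function-stripped (subject terms, relation type,
#' object terms) triple. The count is the number of matching units among the
#' three: the subject slot matches when any gold term in it is equivalent to
#' any predicted term in it, likewise the object slot, and the relation type
#' matches on equality. A full relationship match is a count of 3; the
#' secondary relation level accepts counts of 2 or more.
#'
#' @param g,p Relation fragments (the `relation` slot of
#'   [fragment_statement()]).
#' @inheritParams entities_equivalent
#' @return Integer in 0:3.
#' @export
relation_match_count <- function(g, p, map = NULL) {
  n <- 0L
  if (any_pair_equivalent(g$subject_terms, p$subject_terms, map)) n <- n + 1L
  if (identical(g$relation, p$relation)) n <- n + 1L
  if (any_pair_equivalent(g$object_terms, p$object_terms, map)) n <- n + 1L
  n
}

# Full-statement equivalence: recursive node-by-node agreement under the
# same simplifications (terms relaxed, function types collapsed, tloc
# locations optional, pmod on type only).
nodes_equivalent <- function(a, b, map = NULL, strict_tloc = FALSE) {
  if (is_bel_term(a) && is_bel_term(b)) return(terms_equivalent(a, b, map))
  if (!(is_bel_fn(a) && is_bel_fn(b))) return(FALSE)
  if (a$ftype != b$ftype) return(FALSE)
  if (strict_tloc && a$ftype == "tloc" && !locations_match(a, b, map)) {
    return(FALSE)
  }
  nodes_equivalent(a$inner, b$inner, map, strict_tloc)
}

statements_equivalent <- function(a, b, map = NULL, strict_tloc = FALSE) {
  identical(a$relation, b$relation) &&
    nodes_equivalent(a$subject, b$subject, map, strict_tloc) &&
    nodes_equivalent(a$object, b$object, map, strict_tloc)
}
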