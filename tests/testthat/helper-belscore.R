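# Statements printed verbatim in the track literature (Fig 1 and the
# results discussion), including the typographic quotes of the calcium
# example and the long activity spelling.
verbatim_statements <- c(
  "p (HGNC:IL1B) increases p (HGNC:ATF2, pmod(P))",
  "act(p (HGNC:EDNRA)) increases a (CHEBI:“calcium(2+)”)",
  "p (HGNC:TNF) increases tloc(p (HGNC:KHDRBS1), GOCC:cytoplasm, GOCC:nucleus)",
  "p (MGI:Tmsb4x) decreases path (MESHD:Colitis)",
  "p (HGNC:CXCL8) increases p (HGNC:BCL2)",
  "catalyticActivity (HGNC:XIAP) decreases catalyticActivity (HGNC:CASP9)"
)

# A small three-way ortholog fixture table written to a temp file.
write_fixture_map <- function(rows = c("IL1B\t3553\tIl1b",
                                       "TNF\t7124\tTnf",
                                       "ATF2\t1386\tAtf2")) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("HGNC\tEGID\tMGI", rows), path)
  path
}

# Exhaustive maximum-matching oracle: tries every injective assignment of
# gold to compatible pred fragments and returns the largest size.
brute_force_matching <- function(gold, pred, predicate) {
  n_p <- length(pred)
  adj <- lapply(gold, function(g) {
    which(vapply(pred, function(p) isTRUE(predicate(g, p)), logical(1)))
  })
  rec <- function(i, used) {
    if (i > length(adj)) return(0L)
    best <- rec(i + 1L, used)
    for (j in adj[[i]]) {
      if (!used[[j]]) {
        used[[j]] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[[j]] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, n_p))
}

# Random gene-product term over a tiny vocabulary with cross-namespace
# overlap, so equivalence classes collide and matching order matters.
random_gene_term <- function(n_ids = 3) {
  ns <- sample(c("HGNC", "EGID", "MGI"), 1L)
  idx <- sample.int(n_ids, 1L)
  value <- switch(ns, HGNC = paste0("GENE", idx),
                  EGID = as.character(1000L + idx),
                  MGI = paste0("Gene", idx))
  parse_term(sprintf("%s(%s:%s)", sample(c("p", "g", "r"), 1L), ns, value))
}

# Equivalence fixture connecting GENE<i>/100<i>/Gene<i> across namespaces.
overlap_map <- function(n_ids = 3) {
  rows <- vapply(seq_len(n_ids), function(i) {
    sprintf("GENE%d\t%d\tGene%d", i, 1000L + i, i)
  }, character(1))
  load_equivalence_map(write_fixture_map(rows))
}

all_error_kinds <- c("entity_swap", "namespace_swap", "relation_flip",
                     "subject_object_swap", "function_drop", "function_add",
                     "abundance_change", "invalidate_syntax",
                     "drop_statement")

counts_of <- function(evaluation) {
  as.data.frame(tidy(evaluation)[, c("level", "tp", "fp", "fn")])
}
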