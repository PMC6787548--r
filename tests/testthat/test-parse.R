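test_that("the protein phosphorylation statement parses to the expected tree", {
  s <- parse_statement("p (HGNC:IL1B) increases p (HGNC:ATF2, pmod(P))")
  expect_s3_class(s, "bel_statement")
  expect_equal(s$relation, "increases")
  expect_equal(s$subject$abundance, "p")
  expect_equal(s$subject$entity$namespace, "HGNC")
  expect_equal(s$subject$entity$value, "IL1B")
  # the pmod argument wraps the object term in a function node
  expect_s3_class(s$object, "bel_fn")
  expect_equal(s$object$ftype, "pmod_P")
  expect_equal(s$object$inner$entity$value, "ATF2")
  expect_equal(s$raw_text, "p (HGNC:IL1B) increases p (HGNC:ATF2, pmod(P))")
})

test_that("activity, translocation and quoted chemical values parse", {
  s <- parse_statement("act(p (HGNC:EDNRA)) increases a (CHEBI:“calcium(2+)”)")
  expect_equal(s$subject$ftype, "act")
  expect_equal(s$subject$inner$entity$value, "EDNRA")
  expect_equal(s$object$abundance, "a")
  expect_equal(s$object$entity$value, "calcium(2+)")

  s <- parse_statement(
    "p (HGNC:TNF) increases tloc(p (HGNC:KHDRBS1), GOCC:cytoplasm, GOCC:nucleus)")
  expect_equal(s$object$ftype, "tloc")
  expect_equal(s$object$inner$entity$value, "KHDRBS1")
  expect_equal(s$object$from_loc$value, "cytoplasm")
  expect_equal(s$object$to_loc$value, "nucleus")
})

test_that("every statement printed verbatim in the track report parses and validates", {
  for (txt in verbatim_statements) {
    expect_no_error(parse_statement(txt))
    expect_true(validate_statement(txt)$valid, label = txt)
  }
})

test_that("long function names and activity subtypes are accepted and collapsed", {
  s <- parse_statement(
    "catalyticActivity (HGNC:XIAP) decreases catalyticActivity (HGNC:CASP9)")
  expect_equal(s$subject$ftype, "act")
  expect_equal(s$subject$subtype, "cat")
  expect_equal(serialize_statement(s), "cat(p(HGNC:XIAP)) decreases cat(p(HGNC:CASP9))")
  long <- parse_statement(
    "proteinAbundance(hgnc:IL1B) increases biologicalProcess(GOBP:inflammation)")
  expect_equal(serialize_statement(long),
               "p(HGNC:IL1B) increases bp(GOBP:inflammation)")
})

test_that("syntax errors carry a position and a specific message", {
  expect_error(parse_statement("p(HGNC:IL1B) increases"),
               class = "bel_parse_error")
  err <- tryCatch(parse_statement("p(HGNC:IL1B) increases"),
                  bel_parse_error = function(e) e)
  expect_true(err$position > nchar("p(HGNC:IL1B) increases") - 1)

  expect_error(parse_statement("p(HGNC:IL1B increases p(HGNC:ATF2)"),
               class = "bel_parse_error")
  expect_error(parse_statement("p(XXX:IL1B) increases p(HGNC:ATF2)"),
               regexp = "unknown namespace")
  expect_error(parse_statement("q(HGNC:TNF) increases p(HGNC:ATF2)"),
               regexp = "unknown function")
  expect_error(parse_statement("p(HGNC:A) correlates p(HGNC:B)"),
               regexp = "relation")
  expect_error(parse_statement(""), regexp = "empty input")
})

test_that("parse_term handles terms, complexes and rejects unknown functions", {
  t1 <- parse_term("path (MESHD:Colitis)")
  expect_equal(t1$abundance, "path")
  expect_equal(t1$entity$namespace, "MESHD")

  cx <- parse_term("complex(p(HGNC:A), p(HGNC:B))")
  expect_equal(cx$abundance, "complex")
  expect_length(cx$members, 2)
  expect_error(parse_term("complex(p(HGNC:A))"), regexp = "complex")
  expect_error(parse_term("q(HGNC:TNF)"), regexp = "unknown function")
  named <- parse_term("complex(GOCC:\"proteasome complex\")")
  expect_null(named$members)
  expect_equal(named$entity$namespace, "GOCC")
})

test_that("relation normalization maps word and arrow variants", {
  expect_equal(normalize_relation("directly increases"), "increases")
  expect_equal(normalize_relation("directly decreases"), "decreases")
  expect_equal(normalize_relation("->"), "increases")
  expect_equal(normalize_relation("=>"), "increases")
  expect_equal(normalize_relation("-|"), "decreases")
  expect_equal(normalize_relation("=|"), "decreases")
  expect_equal(normalize_relation("decreases"), "decreases")
  expect_error(normalize_relation("correlates"), class = "bel_parse_error")
  # arrow spellings inside a statement line
  s <- parse_statement("p(HGNC:A) -| p(HGNC:B)")
  expect_equal(s$relation, "decreases")
  s <- parse_statement("p(HGNC:A) directly increases p(HGNC:B)")
  expect_equal(s$relation, "increases")
})

test_that("serialization is canonical and round-trips", {
  canon <- "p(HGNC:IL1B) increases p(HGNC:ATF2, pmod(P))"
  s <- parse_statement("p (HGNC:IL1B) increases p (HGNC:ATF2, pmod(P))")
  expect_equal(serialize_statement(s), canon)
  expect_equal(serialize_statement(parse_statement(canon)), canon)
  # quoting appears exactly when the value needs it
  expect_equal(serialize_term(parse_term("a(CHEBI:“calcium(2+)”)")),
               'a(CHEBI:"calcium(2+)")')
  expect_equal(serialize_term(parse_term('a(CHEBI:"water")')), "a(CHEBI:water)")
})

test_that("parse/serialize identity holds over generated statements", {
  corpus <- generate_corpus(400, seed = 421)
  resers <- vapply(corpus$statement,
                   function(x) serialize_statement(parse_statement(x)),
                   character(1), USE.NAMES = FALSE)
  expect_identical(resers, corpus$statement)
})

test_that("validator and parser agree on validity", {
  good <- generate_corpus(50, seed = 5)$statement
  bad <- c("", "p(HGNC:A increases p(HGNC:B)", "p(HGNC:A) increases",
           "complex(p(HGNC:A)) increases p(HGNC:B)")
  for (txt in good) {
    expect_true(validate_statement(txt)$valid)
    expect_no_error(parse_statement(txt))
  }
  for (txt in bad) {
    expect_false(validate_statement(txt)$valid)
    expect_error(parse_statement(txt), class = "bel_parse_error")
  }
})

test_that("namespace-abundance incompatibilities are reported as data", {
  v <- validate_statement("bp(HGNC:TNF) increases p(HGNC:ATF2)")
  expect_false(v$valid)
  expect_match(v$errors$message[[1]], "bp\\(\\)")
  # exhaustive cross-product of single-entity abundances and namespaces
  allowed <- list(p = c("HGNC", "MGI", "EGID"), g = c("HGNC", "MGI", "EGID"),
                  r = c("HGNC", "MGI", "EGID"), a = "CHEBI", bp = "GOBP",
                  path = "MESHD")
  nss <- c("HGNC", "MGI", "EGID", "CHEBI", "MESHD", "GOBP", "GOCC")
  for (ab in names(allowed)) {
    for (ns in nss) {
      txt <- sprintf("%s(%s:X1) increases p(HGNC:ATF2)", ab, ns)
      expect_equal(validate_statement(txt)$valid, ns %in% allowed[[ab]],
                   label = txt)
    }
  }
  v <- validate_statement("p(HGNC:TNF) increases tloc(p(HGNC:A), MESHD:x, GOCC:y)")
  expect_false(v$valid)
  expect_match(v$errors$message[[1]], "GOCC")
  expect_false(validate_statement("")$valid)
})
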