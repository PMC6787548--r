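test_that("fragment matching yields TP/FP/FN with maximum-matching credit", {
  gold <- lapply(c("p(HGNC:IL1B)", "p(HGNC:ATF2)"), parse_term)
  same <- match_fragments(gold, gold)
  expect_equal(c(same$tp, same$fp, same$fn), c(2, 0, 0))

  partial <- match_fragments(gold, lapply("p(HGNC:IL1B)", parse_term))
  expect_equal(c(partial$tp, partial$fp, partial$fn), c(1, 0, 1))

  extra <- match_fragments(lapply("p(HGNC:A1)", parse_term),
                           lapply(c("p(HGNC:B1)", "p(HGNC:A1)"), parse_term))
  expect_equal(c(extra$tp, extra$fp, extra$fn), c(1, 1, 0))
})

test_that("matching equals the exhaustive enumeration oracle on small instances", {
  set.seed(2024)
  m <- overlap_map()
  pred_fun <- function(a, b) terms_equivalent(a, b, m)
  for (case in 1:120) {
    n_g <- sample(0:6, 1)
    n_p <- sample(0:6, 1)
    gold <- replicate(n_g, random_gene_term(), simplify = FALSE)
    pred <- replicate(n_p, random_gene_term(), simplify = FALSE)
    got <- match_fragments(gold, pred, predicate = pred_fun)
    want_tp <- brute_force_matching(gold, pred, pred_fun)
    expect_equal(got$tp, want_tp)
    expect_equal(got$fp, n_p - want_tp)
    expect_equal(got$fn, n_g - want_tp)
  }
})

test_that("precision, recall and F follow the micro definitions", {
  one <- precision_recall_f(tibble::tibble(tp = 117, fp = 265, fn = 40))
  expect_equal(one$precision, 117 / 382, tolerance = 1e-12)
  zero <- precision_recall_f(tibble::tibble(tp = 0, fp = 0, fn = 0))
  expect_equal(c(zero$precision, zero$recall, zero$f_score), c(0, 0, 0))
  # P = R = x implies F = x
  eq <- precision_recall_f(tibble::tibble(tp = 3, fp = 2, fn = 2))
  expect_equal(eq$f_score, eq$precision)
  # F lies between P and R
  x <- precision_recall_f(tibble::tibble(tp = 10, fp = 5, fn = 30))
  expect_gte(x$f_score, min(x$precision, x$recall))
  expect_lte(x$f_score, max(x$precision, x$recall))
})

test_that("a wrong relation keeps term credit but loses relation and statement", {
  gold <- tibble::tibble(evidence_id = "e1",
    statement = "p(HGNC:IL1B) increases p(HGNC:ATF2, pmod(P))")
  pred <- tibble::tibble(evidence_id = "e1",
    statement = "p(HGNC:IL1B) decreases p(HGNC:ATF2)")
  got <- counts_of(evaluate_corpus(gold, pred))
  want <- data.frame(
    level = c("Term", "Function", "Function-Secondary", "Relation",
              "Relation-Secondary", "Statement"),
    tp = c(2L, 0L, 0L, 0L, 1L, 0L),
    fp = c(0L, 0L, 0L, 1L, 0L, 1L),
    fn = c(0L, 1L, 1L, 1L, 0L, 1L))
  expect_equal(got, want)
})

test_that("identity and empty prediction corpora score 1 and 0", {
  gold <- generate_corpus(15, seed = 31)
  perfect <- evaluate_corpus(gold, gold)
  expect_true(all(abs(tidy(perfect)$precision - 1) < 1e-12))
  expect_true(all(abs(tidy(perfect)$recall - 1) < 1e-12))
  expect_true(all(abs(tidy(perfect)$f_score - 1) < 1e-12))

  none <- evaluate_corpus(gold,
    tibble::tibble(evidence_id = character(), statement = character()))
  expect_true(all(tidy(none)$recall == 0))
  expect_true(all(tidy(none)$fp == 0))
})

test_that("invalid predicted statements are ignored, not penalized as FP", {
  gold <- tibble::tibble(evidence_id = "e1",
                         statement = "p(HGNC:A1) increases p(HGNC:B1)")
  pred <- tibble::tibble(evidence_id = "e1",
                         statement = c("p(HGNC:A1 increases p(HGNC:B1)",
                                       "bp(HGNC:A1) increases p(HGNC:B1)"))
  ev <- evaluate_corpus(gold, pred)
  expect_equal(ev$ignored_invalid, 2L)
  got <- counts_of(ev)
  expect_true(all(got$fp == 0))
  expect_equal(got$fn, c(2L, 0L, 0L, 1L, 1L, 1L))
})

test_that("prediction-only evidence ids warn and contribute false positives", {
  gold <- tibble::tibble(evidence_id = "e1",
                         statement = "p(HGNC:A1) increases p(HGNC:B1)")
  pred <- tibble::tibble(evidence_id = c("e1", "e9"),
                         statement = c("p(HGNC:A1) increases p(HGNC:B1)",
                                       "p(HGNC:C1) increases p(HGNC:D1)"))
  expect_warning(ev <- evaluate_corpus(gold, pred), regexp = "absent")
  got <- counts_of(ev)
  expect_equal(got[got$level == "Statement", "fp"], 1L)
  expect_equal(got[got$level == "Term", "fp"], 2L)
})

test_that("swapping gold and prediction corpora exchanges P and R exactly", {
  a <- generate_corpus(20, seed = 41)
  bp <- perturb(a, c("entity_swap", "function_drop"), c(0.3, 0.2), seed = 42)
  b <- bp$pred
  b <- b[vapply(b$statement, function(x) validate_statement(x)$valid,
                logical(1)), ]
  fwd <- tidy(evaluate_corpus(a, b))
  rev <- tidy(evaluate_corpus(b, a))
  expect_equal(fwd$precision, rev$recall, tolerance = 1e-12)
  expect_equal(fwd$recall, rev$precision, tolerance = 1e-12)
  expect_equal(fwd$f_score, rev$f_score, tolerance = 1e-12)
})

test_that("repeated identical fragments carry no extra credit", {
  gold <- tibble::tibble(evidence_id = "e1",
                         statement = "p(HGNC:A1) increases p(HGNC:B1)")
  pred <- tibble::tibble(evidence_id = "e1",
                         statement = rep("p(HGNC:A1) increases p(HGNC:B1)", 3))
  got <- counts_of(evaluate_corpus(gold, pred))
  expect_true(all(got$fp == 0))
  expect_true(all(got$fn == 0))
})

test_that("report formatting rounds percentages half up to two decimals", {
  gold <- tibble::tibble(evidence_id = "e1",
                         statement = "p(HGNC:A1) increases p(HGNC:B1)")
  ev <- evaluate_corpus(gold, gold)
  lines <- format_report(ev)
  expect_match(lines[2], "^Term\\s+100\\.00\\s+100\\.00\\s+100\\.00")
  # the rounding rule itself: half-up on the percent scale
  expect_equal(belscore:::round_half_up(49.596, 2), 49.6)
  expect_equal(belscore:::round_half_up(30.625, 2), 30.63)
  expect_equal(belscore:::percent2(0.49596), "49.60")
  expect_equal(belscore:::percent2(0), "0.00")
})

test_that("macro averaging is available alongside micro", {
  gold <- generate_corpus(10, seed = 8)
  pp <- perturb(gold, "relation_flip", 0.5, seed = 9)
  ev <- evaluate_corpus(gold, pp$pred, macro = TRUE)
  expect_false(is.null(ev$macro_levels))
  # with one statement per evidence, macro statement precision is the share
  # of evidences predicted exactly right
  stmt <- ev$macro_levels[ev$macro_levels$level == "Statement", ]
  expect_equal(stmt$precision,
               sum(pp$log$error_kind == "none") / nrow(gold))
})

test_that("tidy, glance and autoplot work on evaluations", {
  gold <- generate_corpus(5, seed = 3)
  ev <- evaluate_corpus(gold, gold)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1)
  expect_equal(glance(ev)$statement_f, 1)
  expect_s3_class(autoplot(ev), "ggplot")
})
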