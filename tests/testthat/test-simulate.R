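test_that("generation is deterministic under a seed and respects rates", {
  a <- generate_corpus(10, seed = 7)
  b <- generate_corpus(10, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_corpus(10, seed = 8)))

  nofun <- generate_corpus(50, function_rates = c(act = 0), seed = 3)
  n_fns <- vapply(nofun$statement, function(x)
    length(fragment_statement(parse_statement(x))$functions), integer(1))
  expect_true(all(n_fns == 0))

  expect_error(generate_corpus(5, vocab_size = 2), regexp = "vocab_size")
})

test_that("the relation ratio tracks the configured increases share", {
  corpus <- generate_corpus(1000, seed = 99)
  n_inc <- sum(grepl(" increases ", corpus$statement, fixed = TRUE))
  p <- 130 / 198
  # within 3 binomial standard deviations of the configured ratio
  expect_lt(abs(n_inc - 1000 * p), 3 * sqrt(1000 * p * (1 - p)))
})

test_that("generated corpora are entirely valid", {
  corpus <- generate_corpus(80, seed = 13)
  ok <- vapply(corpus$statement, function(x) validate_statement(x)$valid,
               logical(1))
  expect_true(all(ok))
})

test_that("perturbation is deterministic and rate 0 is the identity", {
  gold <- generate_corpus(15, seed = 1)
  p1 <- perturb(gold, "entity_swap", 0.5, seed = 2)
  p2 <- perturb(gold, "entity_swap", 0.5, seed = 2)
  expect_identical(p1$pred, p2$pred)
  expect_identical(p1$log, p2$log)

  p0 <- perturb(gold, "entity_swap", 0, seed = 2)
  expect_equal(p0$pred$statement, gold$statement)
  expect_true(all(p0$log$error_kind == "none"))
  got <- counts_of(evaluate_corpus(gold, p0$pred))
  expect_true(all(got$fp == 0) && all(got$fn == 0))

  expect_error(perturb(gold, "typo_kind", 1), regexp = "unknown error_kind")
  expect_error(expected_counts(tibble::tibble(
    evidence_id = "e", error_kind = "typo", n_terms = 2, n_functions = 0)),
    regexp = "unknown error_kind")
})

test_that("evaluator output equals analytic expected counts for every error kind", {
  for (kind in all_error_kinds) {
    gold <- generate_corpus(30, seed = 101)
    pp <- perturb(gold, kind, 1, seed = 202)
    got <- counts_of(suppressWarnings(evaluate_corpus(gold, pp$pred)))
    expect_equal(got, as.data.frame(pp$expected), label = kind)
  }
})

test_that("relation flips at rate 1 keep term credit and secondary relations", {
  gold <- generate_corpus(20, seed = 55)
  pp <- perturb(gold, "relation_flip", 1, seed = 56)
  exp <- pp$expected
  expect_equal(exp$tp[exp$level == "Statement"], 0L)
  expect_equal(exp$tp[exp$level == "Relation"], 0L)
  expect_equal(exp$tp[exp$level == "Relation-Secondary"], 20L)
  expect_equal(exp$fn[exp$level == "Term"], 0L)
})

test_that("syntax invalidation at rate 1 leaves only false negatives", {
  gold <- generate_corpus(20, seed = 60)
  pp <- perturb(gold, "invalidate_syntax", 1, seed = 61)
  ev <- evaluate_corpus(gold, pp$pred)
  expect_equal(ev$ignored_invalid, 20L)
  got <- counts_of(ev)
  expect_true(all(got$fp == 0))
  expect_equal(got$tp, rep(0L, 6))
  expect_equal(got, as.data.frame(pp$expected))
})

test_that("evaluator matches expected counts over mixed-rate random runs", {
  rates <- rep(0.09, length(all_error_kinds))
  for (seed in 1:25) {
    gold <- generate_corpus(20, seed = seed)
    pp <- perturb(gold, all_error_kinds, rates, seed = seed + 5000)
    got <- counts_of(suppressWarnings(evaluate_corpus(gold, pp$pred)))
    expect_equal(got, as.data.frame(pp$expected),
                 label = sprintf("seed %d", seed))
  }
})

test_that("expected counts are additive over the log and zero for empty logs", {
  gold <- generate_corpus(12, seed = 70)
  pp <- perturb(gold, c("relation_flip", "function_drop"), c(0.4, 0.4),
                seed = 71)
  total <- expected_counts(pp$log)
  parts <- lapply(seq_len(nrow(pp$log)), function(i) expected_counts(pp$log[i, ]))
  summed <- Reduce(function(a, b) {
    a$tp <- a$tp + b$tp; a$fp <- a$fp + b$fp; a$fn <- a$fn + b$fn; a
  }, parts)
  expect_equal(total, summed)

  empty_log <- pp$log[0, ]
  z <- expected_counts(empty_log)
  expect_true(all(z$tp == 0) && all(z$fp == 0) && all(z$fn == 0))
})

test_that("cascade monotonicity and conservation hold on every fixture run", {
  for (seed in 1:10) {
    gold <- generate_corpus(15, seed = seed)
    pp <- perturb(gold, all_error_kinds, rep(0.08, length(all_error_kinds)),
                  seed = seed + 900)
    ev <- suppressWarnings(evaluate_corpus(gold, pp$pred))
    w <- function(lv, col) ev$levels[[col]][ev$levels$level == lv]
    expect_lte(w("Statement", "tp"), w("Relation", "tp"))
    expect_lte(w("Relation", "tp"), w("Relation-Secondary", "tp"))
    expect_lte(w("Function", "tp"), w("Function-Secondary", "tp"))
    # conservation: tp + fn = gold fragments, per level
    gold_frags <- expected_counts(pp$log)
    expect_equal(ev$levels$tp + ev$levels$fn, gold_frags$tp + gold_frags$fn)
    # per-evidence monotonicity
    pe <- ev$per_evidence
    for (eid in unique(pe$evidence_id)) {
      sub <- pe[pe$evidence_id == eid, ]
      g <- function(lv) sub$tp[sub$level == lv]
      expect_lte(g("Statement"), g("Relation"))
      expect_lte(g("Relation"), g("Relation-Secondary"))
      expect_lte(g("Function"), g("Function-Secondary"))
    }
  }
})

test_that("sentences with no correct prediction are counted per level", {
  gold <- generate_corpus(10, seed = 80)
  pp <- perturb(gold, "relation_flip", 1, seed = 81)
  ev <- evaluate_corpus(gold, pp$pred)
  nc <- ev$no_correct
  expect_equal(nc$sentences[nc$level == "Relation"], 10L)
  expect_equal(nc$sentences[nc$level == "Term"], 0L)
  expect_equal(nc$sentences[nc$level == "Statement"], 10L)
})
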