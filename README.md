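# belscore

Cascade evaluation of Biological Expression Language (BEL) statement
extraction.

Automatic extraction of causal biological relationships from the literature
is typically benchmarked by asking systems to translate an evidence sentence
into a BEL statement — a triple `subject relation object` over normalized
entities such as `p(HGNC:IL1B) increases p(HGNC:ATF2, pmod(P))` ("IL-1β
increases phosphorylated ATF2"). Because a full statement combines named
entity recognition, normalization to seven namespaces (HGNC, MGI, EGID,
CHEBI, MESHD, GOBP, GOCC), function assignment (`act()`, `pmod(P)`,
`tloc()`, `deg()`, `complex()`) and causal-relation typing, an
all-or-nothing score hides *where* systems fail. belscore implements the
cascade evaluation used for this task: every predicted statement is cut
into fragments and scored at six levels, with partial-credit "secondary"
variants, so term recognition, function extraction and relation typing are
measured separately. It is written for developers of biomedical relation
extraction systems and for organizers of shared-task style evaluations.

## The scoring model

For each evidence sentence, gold and predicted statements are decomposed
into fragments and matched under the track's equivalence simplifications:

| Level | Unit scored | Match condition |
|---|---|---|
| Term | every leaf term (complex members individually + the complex) | namespace/identifier equivalence; `p`/`g`/`r` interchangeable for genes; a complex matches on ≥ 1 member |
| Function | (function type, inner term) | type equal (activity subtypes collapse to `act`), inner term equivalent; `tloc` locations ignored by default; `pmod` on modification type only |
| Function-Secondary | function type alone | type equal |
| Relation | function-stripped (subject, relation, object) | all three units match |
| Relation-Secondary | same | ≥ 2 of 3 units match |
| Statement | the full tree | node-by-node equivalence |

Gene identifiers may be given in HGNC, EntrezGene or mouse-ortholog MGI
form when a cross-namespace equivalence table is supplied. Within each
evidence unit, fragments are deduplicated and the true-positive count is
the size of a **maximum bipartite matching** between gold and predicted
fragments, so credit never depends on input order. Counts are
micro-averaged: TP/FP/FN are summed over the corpus, then

P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R).

Syntactically invalid predictions are ignored (they are neither rewarded
nor penalized), matching the behaviour of the original online validator.

The package also evaluates the companion retrieval task (given a BEL
statement, find up to 10 supporting sentences): micro precision under a
"fully supportive" and a "partially supportive" criterion, mean average
precision over the rankings, Cohen's kappa between annotators, and the
weighted classifier-score combination `0.4·P_EE + 0.5·P_FE + 0.1·P_R`.

## Worked example

```r
library(belscore)

gold <- tibble::tibble(
  evidence_id = "BEL:201720027",
  statement   = "p (HGNC:IL1B) increases p (HGNC:ATF2, pmod(P))")
pred <- tibble::tibble(
  evidence_id = "BEL:201720027",
  statement   = "p(HGNC:IL1B) decreases p(HGNC:ATF2)")

evaluate_corpus(gold, pred)
#> Level                       F        P        R     TP     FP     FN
#> Term                   100.00   100.00   100.00      2      0      0
#> Function                 0.00     0.00     0.00      0      0      1
#> Function-Secondary       0.00     0.00     0.00      0      0      1
#> Relation                 0.00     0.00     0.00      0      1      1
#> Relation-Secondary     100.00   100.00   100.00      1      0      0
#> Statement                0.00     0.00     0.00      0      1      1
```

The prediction found both terms (Term = 100%), missed the phosphorylation
function (Function/Function-Secondary FN), and flipped the causal
direction, so the relation keeps secondary credit (2 of 3 units correct)
but loses the full relation and the statement. `tidy()` returns this table
as a tibble, `glance()` a one-row summary, and `autoplot()` a per-level
bar chart.

A synthetic benchmark with known ground truth:

```r
gold <- generate_corpus(100, seed = 42)
pp   <- perturb(gold, c("relation_flip", "entity_swap"), c(0.2, 0.2), seed = 43)
ev   <- evaluate_corpus(gold, pp$pred)
all.equal(as.data.frame(tidy(ev)[, c("level","tp","fp","fn")]),
          as.data.frame(pp$expected))
#> [1] TRUE
```

`perturb()` injects typed, rate-controlled errors and returns the
analytically expected per-level counts, which the evaluator reproduces
exactly.

A command-line front end is installed at
`system.file("exec", "belscore", package = "belscore")` with subcommands
`evaluate`, `task2-eval`, `fragment`, `validate` and `simulate`.

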