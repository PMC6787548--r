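---
title: "Cascade evaluation of BEL statement extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade evaluation of BEL statement extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belscore)
library(tibble)
```

## The restricted BEL subset

A BEL statement encodes one causal biological relationship as a triple:
a subject, one of two relation types (`increases`, `decreases`) and an
object. Subjects and objects are *terms* — abundance functions over
namespaced entities: `p()` protein (HGNC/MGI/EGID), `a()` chemical
(CHEBI), `bp()` biological process (GOBP), `path()` disease (MESHD) and
`complex()` for protein complexes — optionally wrapped by *functions*:
activity `act()`, phosphorylation `pmod(P)`, translocation `tloc()` and
degradation `deg()`.

```{r}
s <- parse_statement("p (HGNC:IL1B) increases p (HGNC:ATF2, pmod(P))")
serialize_statement(s)
```

The parser is a hand-written recursive descent over this subset. It is
deliberately lenient on surface variation that occurs in real corpora and
submissions, while the serializer emits exactly one canonical spelling:

* whitespace between a function name and `(` is tolerated;
* short and long function names are both accepted (`p` /
  `proteinAbundance`, `act` / `molecularActivity`, ...). Activity
  subtypes such as `catalyticActivity` parse to an `act` node that
  retains the subtype (serialized back as its short form, e.g. `cat`),
  and all subtypes are treated as plain `act` during matching;
* an activity written directly on an entity, `cat(HGNC:XIAP)`, is read
  as shorthand for `cat(p(HGNC:XIAP))` — this spelling occurs in
  published examples;
* straight (`"`) and typographic (`“ ”`) double quotes are both accepted
  around values with special characters; output uses straight quotes, and
  only where the value requires them;
* namespace prefixes are case-insensitive and canonicalized to upper
  case; entity values compare case-insensitively except purely numeric
  identifiers;
* relation spellings `directly increases`, `->`, `=>` (and the
  `decreases` counterparts `-|`, `=|`) normalize to the two canonical
  types.

Validation is separate from parsing and returns errors as data (position
plus message) rather than conditions, mirroring how a submission
validator must behave: `bp()` only with GOBP, `path()` only with MESHD,
`a()` only with CHEBI, `p()/g()/r()` only with the three gene namespaces,
named complexes with GOCC, `tloc()` locations with GOCC, and modification
functions only inside gene-product terms. `sub()` and `trunc()` are
parsed and validated (they occur in training data) but carry no special
matching rule; they participate as generic function fragments.

## The cascade scoring model

Scoring a structured prediction all-or-nothing conflates entity
recognition with relation extraction. The cascade model therefore cuts
every statement into fragments and scores six levels per evidence
sentence:

1. **Term** — every leaf term. A composed complex contributes its
   members individually *and* the complex term itself, so member-level
   credit and the one-correct-member rule are both expressible.
2. **Function** — each function node together with its inner term.
3. **Function-Secondary** — the function type alone.
4. **Relation** — the function-stripped (subject terms, relation,
   object terms) triple; all three units must match.
5. **Relation-Secondary** — two of the three units suffice.
6. **Statement** — full node-by-node equivalence.

Matching applies the track's simplifications at every level: gene
abundances `p/g/r` are interchangeable; HGNC, EntrezGene and MGI
identifiers are interchangeable when a cross-namespace table
(`load_equivalence_map()`) groups them; a composed complex matches when
at least one member pair matches; `pmod` compares the modification type
only; `tloc` matches on its inner term. Two open points are settled as
package policy: `tloc()` locations are ignored by default with a
`strict_tloc` switch to require both GOCC locations, and subject/object
slots match any-vs-any over their stripped term sets (required once a
complex puts several terms into one slot).

Within an evidence unit, fragments are first deduplicated by canonical
spelling — repeated identical fragments earn no extra credit — and the
true-positive count at each level is the size of a **maximum bipartite
matching** between gold and predicted fragments under the level's
equivalence predicate. A greedy matcher would make scores depend on input
order whenever equivalence classes overlap (e.g. two gold orthologs both
compatible with one prediction); the augmenting-path matcher is
order-free, and a test suite checks it against exhaustive enumeration on
all instances up to 6×6.

Counts are micro-averaged (summed over the corpus before computing
precision, recall and F), matching how corpus-level results are reported
for this task; per-evidence macro averages are available via
`macro = TRUE`. Invalid predictions are ignored entirely rather than
counted as false positives: the reported precision then describes the
valid part of a submission, and the `ignored_invalid` count preserves the
information. Printed reports use the percent scale with two decimals,
rounded half up, which reproduces published table values from their
printed inputs.

The per-level count of evidence sentences with gold fragments but zero
true positives (`$no_correct`) supports "which information is never
extracted" analyses.

## The retrieval task

For the inverse task — given a statement, retrieve up to 10 supporting
sentences — sentences are manually graded `fully` supportive (the
sentence alone suffices to curate the statement), `partially` supportive
(context or background knowledge needed) or `not_supportive`. The
partial criterion treats fully supportive sentences as partially
supportive too, so its counts dominate the full criterion by
construction. `micro_precision()` pools all sentences;
`mean_average_precision()` averages per-statement average precision.

AP here normalizes by the number of relevant sentences *retrieved* in
the list, not by all relevant sentences in the corpus — the corpus-wide
relevant count is unknowable from graded submissions alone. This choice
makes MAP values from different normalizations incomparable, so it is
stated prominently; statements with no retrieved relevant sentence (or
no retrieval at all, when the gold statement list is supplied) enter the
mean with AP 0, which prevents gaming the mean by omission.

Inter-annotator agreement uses Cohen's kappa computed from the raw
confusion table; the degenerate case of both annotators constant on one
label is reported as kappa 1 when they agree. The ranking-score
combiner is the published weighted sum of three classifier
probabilities with default weights `w_ee = 0.4`, `w_fe = 0.5`,
`w_r = 0.1` (weights are documented to sum to 1 but this is not
enforced, so re-weighting experiments remain possible).

## The synthetic benchmark generator

Real gold corpora and system submissions for this task are not freely
redistributable, so the package ships a seeded generator whose defaults
emulate the composition of the 2017 test corpus: relation types drawn
increases:decreases at 130:68, term classes at the p:a:bp:path
proportions 328:52:23:2, and per-statement function probabilities from
the published function counts over 198 statements (act 79, pmod 36,
tloc 10, deg 4, complex 5). Entities come from per-namespace synthetic
vocabularies (default 50 identifiers per namespace).

Two regularities are imposed by design so that error injection has
exactly computable consequences: each statement carries at most one
function node, applied to a protein slot, and all leaf entities within
one statement are distinct. `perturb()` then applies at most one typed
error per statement (rates must sum to ≤ 1) from a taxonomy mirroring
the cascade levels — `entity_swap`, `namespace_swap`, `relation_flip`,
`subject_object_swap`, `function_drop`, `function_add`,
`abundance_change`, `invalidate_syntax`, `drop_statement` — and derives
the expected per-level TP/FP/FN from the *realized* perturbation log
via a documented delta table, never by running the evaluator. For
example, an entity swap inside a complex breaks one term fragment but
neither the relation slot (another member still matches) nor the
statement (the one-correct-member rule), while an abundance change on a
gene term changes nothing at any level. This makes the
evaluator-vs-expected agreement test exact rather than statistical.

```{r}
gold <- generate_corpus(50, seed = 42)
pp <- perturb(gold, c("relation_flip", "function_drop"), c(0.3, 0.2), seed = 43)
ev <- evaluate_corpus(gold, pp$pred)
all.equal(as.data.frame(tidy(ev)[, c("level", "tp", "fp", "fn")]),
          as.data.frame(pp$expected))
autoplot(ev)
```

What passing these tests shows — and does not show. The generator
produces statements over the real grammar, namespaces and function
inventory with realistic composition, so it exercises the parser,
fragmenter, equivalence rules and matcher end to end. It does not
emulate natural-language sentences, NER offsets, systematic
normalization biases, nested functions, multi-statement sentences or
duplicate fragments across statements; agreement on synthetic corpora
therefore validates the scoring machinery, not extraction difficulty on
real text.

## Numerical and interface choices

* Percentages are rounded half away from zero at two decimals (base R
  `round()` is half-to-even and would print some published values
  differently).
* Empty denominators give 0 for precision, recall and F (the convention
  of an empty submission scoring zero, not NA).
* Character offsets in entity annotation files are 0-based and
  half-open, checked against the sentence when a corpus is supplied.
* The BioC dialect stores one document per evidence sentence with the
  statement text in an annotation infon keyed `bel`; the reader/writer
  pair defines and round-trips this dialect.
* Test suites and the acceptance script use moderate problem sizes
  (10^4 statements for the round-trip property, 25-statement corpora
  across ~50 seeded perturbation runs, 200 matching-oracle instances up
  to 6×6), chosen to give dense coverage of the combinatorics at
  interactive runtimes.

## Known limitations

* Only the track's restricted grammar is covered — no `reaction()`,
  `fusion()`, gene variants, nested statements-as-objects, or full
  OpenBEL compatibility.
* No ortholog table ships with the package; without a user-supplied
  table, cross-namespace gene matching falls back to exact identity
  (this avoids baking in a particular database release).
* Whether the original evaluation accepted activity subtypes as
  distinct functions is not documented; the package collapses them to
  `act`, keeping the parsed subtype on the node for downstream use.
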