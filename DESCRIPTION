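Package: belscore
Title: Cascade Evaluation of Biological Expression Language Statement Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parser, validator and canonical serializer for the restricted
    Biological Expression Language (BEL) subset used in community evaluations
    of biomedical relation extraction, together with the cascade
    (multi-level) scorer that compares predicted against gold BEL statements
    at term, function, relation and full-statement levels with
    namespace-equivalence simplifications, an evaluator for ranked
    evidence-sentence retrieval (micro precision, mean average precision,
    inter-annotator kappa, weighted ranking scores), BioC XML and
    tab-separated corpus readers and writers, and a seeded synthetic
    gold/prediction corpus generator with typed error injection and
    analytically known expected counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
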