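Package: termmapr
Title: Rule-Based Cross-Mapping of Clinical Term Banks to Coded Nursing Terminologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated cross-mapping between a free-text bank of clinical
    terms and a coded, axis-tagged target terminology (ICNP-style seven-axis
    primitive concepts). Implements a two-phase pipeline: text normalization
    (accent stripping, special-character removal, lowercasing, stopword
    removal) followed by a cascade of six natural-language-processing
    matching rules (exact, lemma, stem, synonym, restricted, comprehensive)
    scored with Levenshtein percent similarity, with 90-99 percent near
    misses collected as candidate terms for expert review. Also provides the
    manual-versus-automated comparison framework (equality/exclusivity
    bookkeeping, truncated agreement percentages, ISO/TR 12300-style
    equivalence-degree aggregation) and a seeded synthetic-fixture generator
    that plants each relationship category with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
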