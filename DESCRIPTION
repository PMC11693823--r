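Package: bivocab
Title: Cognateness and Bilingual Vocabulary Acquisition with Bayesian
    Ordinal Item-Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how phonological similarity between
    translation equivalents (cognateness) shapes early bilingual
    vocabulary acquisition from caregiver checklist data. Provides X-SAMPA
    phoneme tokenization and length-normalized Levenshtein cognateness
    scoring, Zipf lexical-frequency and language-exposure predictor
    construction, the item filtering cascade and ordinal response
    encoding, a Bayesian multilevel cumulative-logit item-response model
    fitted with a built-in No-U-Turn sampler, posterior summaries via
    highest-density intervals and a region of practical equivalence on the
    probability scale, and synthetic-data generators (direct draws from
    the ordinal model, and an accumulator-with-co-activation simulator of
    bilingual word learning) for parameter-recovery and theory-direction
    checks.
License: MIT + file LICENSE
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    coda,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
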