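Package: cadindex
Title: Composite Anxiety and Depression Index from Search Trends
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds a Public Opinion Dictionary (POD) of anxiety- and
    depression-related words from an emotion-rich text corpus, scores each
    word's relevance to the target words with CBOW word embeddings, and
    synthesizes the Composite Anxiety and Depression Index (CADI): a
    region-by-year mental-health surveillance index combining
    population-adjusted search trends through efficacy-coefficient (min-max)
    weighting, rescaled by the year-over-year Internet penetration ratio.
    Includes a synthetic-data generator with planted latent severity for
    end-to-end validation, weighted-prevalence survey validation with a
    Pearson/Kendall/Spearman correlation suite, and an association layer
    (linear and median regression with year dummies and per-capita-GDP
    subgroups).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
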