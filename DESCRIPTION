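Package: yeastlure
Title: Attraction Statistics for Yeast-Volatile Choice Assays and Field Trapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for two-choice (T-maze) olfactometer assays of
    insect attraction to yeast volatiles and for blocked field-trap counts.
    Computes Attraction Indices from arm counts, pooled exact binomial choice
    tests, deviance (likelihood-ratio) tests from binomial logistic regression,
    two-way ANOVA on attraction, a permutation-constructed additive null for
    blends of volatiles with a complementary linear-model contrast,
    Kruskal-Wallis and Dunn post-hoc tests with Benjamini-Hochberg adjustment
    and compact-letter grouping, and Poisson generalised linear models with
    block structure and estimated-marginal-mean confidence intervals. Includes
    seeded synthetic-data generators that emulate the assay structure so every
    stage can be exercised end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    car,
    emmeans,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
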