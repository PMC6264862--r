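Package: diarystrat
Title: Stratification of Binary Symptom Diaries by Shape- and Pattern-Based Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing daily binary symptom diaries from paediatric
    cohort studies. Simulates diary cohorts with seasonal symptom prevalence,
    multi-day illness episodes, symptom co-occurrence and burden-independent
    dropout; applies per-month missingness tolerance rules to decide which
    diaries enter each representation; builds a calendar-aligned
    children x symptoms x months tensor of monthly symptom proportions
    (shape representation) and a diary-year x daily-symptom-combination
    frequency matrix (pattern representation); and fits three unsupervised
    stratification models from scratch: non-negative matrix factorization by
    multiplicative updates, INDSCAL three-way scaling of pointwise
    dissimilarities by constrained alternating least squares, and latent
    Dirichlet allocation by collapsed Gibbs sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    pracma,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
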