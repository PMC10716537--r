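Package: crsig
Title: Tissue-Independent Transcriptomic Signatures of Calorie Restriction
    via Ensemble Attribute Weighting
Version: 0.1.0
Authors@R:
    person("crsig", "developers", email = "crsig@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for deriving tissue-independent
    transcriptomic signatures of calorie restriction from gene-expression
    count data. Seven attribute-weighting (feature-selection) algorithms
    (information gain, gain ratio, single-rule accuracy, chi-squared, Gini
    index, symmetric uncertainty, Relief) score genes and the categorical
    tissue attribute against the treatment label; normalized weights are
    summed into an ensemble ranking from which a top-k signature is drawn.
    Supporting stages include negative-binomial Wald differential
    expression with Benjamini-Hochberg correction, correlation-matrix PCA
    evaluation of the signature, Bayesian two-group effect summaries
    (posterior median, highest-density interval, probability of direction,
    ROPE proportion), confidence-weighted literature-relation networks with
    greedy drug-combination selection, and seeded synthetic-data generators
    so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
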