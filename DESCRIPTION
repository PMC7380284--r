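Package: evotiss
Title: Tissue-Anchored Analysis of Protein Sequence Evolution from
    Multi-Tissue Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating multi-tissue gene expression features to
    protein evolutionary rate (dN/dS). Computes per-tissue expression
    moments, the tau expression-breadth statistic, and each gene's
    MaxTissue/MaxVariance (the tissue of maximum inter-individual
    expression variance); tests the tissue-anchored model of evolutionary
    rate with a gene-count-preserving permutation Kruskal-Wallis test and
    the MaxTissue-delta dispersion metric; provides Empirical Partial Rank
    Correlation Analysis (EPRCA) for testing independent effects under
    noisy conditioning variables, generalized least squares under a known
    co-expression covariance, branch- and degree-preserving permutation
    nulls, gradient-boosted joint modeling of evolutionary rate with
    feature-importance spectra, and statistical power calculations for
    transcriptome-wide association studies. Includes a synthetic
    multi-tissue expression generator so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    matrixStats
Config/testthat/edition: 3
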