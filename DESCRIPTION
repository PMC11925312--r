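Package: pcgem
Title: Proteome-Constrained Genome-Scale Metabolic Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analyzing proteome-constrained genome-scale
    metabolic models (GEMs), motivated by the metabolism of the mature human red
    blood cell. Provides a lightweight GEM data model with SBML (Level 3 + fbc)
    and flat-table input/output, flux balance and flux variability analysis on a
    compiled bounded-variable simplex, mass and charge balance reports, network
    connectivity statistics with currency-metabolite pruning, construction of
    proteome-constrained models from protein and complex tables (partitioned
    hemoglobin/low-abundance proteome budgets, molar-mass-scaled effective rate
    constants), weighted quadratic-programming fitting of measured proteomes,
    slack-relaxed context-specific models, proteome-constrained flux variability
    analysis, Spearman-based classification of reactions by enzyme-abundance
    dependence, and a synthetic data generator for donor proteome panels with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    quadprog,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
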