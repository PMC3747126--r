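Package: crpewas
Title: Sibship-Aware Epigenome-Wide Association Analysis of DNA
    Methylation and Serum C-Reactive Protein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An epigenome-wide association study (EWAS) pipeline for
    Infinium-style methylation arrays in sibship-based cohorts, built around
    serum C-reactive protein as the inflammatory outcome.  Provides
    control-probe based sample quality control, a Hartigan-Hartigan dip test
    for multimodal probe filtering, control-probe principal-component
    normalization of methylated/unmethylated intensities, per-site linear
    mixed models with sibship random intercepts, genomic-inflation
    diagnostics with methylome principal-component adjustment, an internal
    replication design that splits sibships into two unrelated subsets, and
    hypergeometric gene-set over-representation.  A synthetic-data generator
    emulates the statistical structure of a hypertensive sibship cohort so
    that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
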