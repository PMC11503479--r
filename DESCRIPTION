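Package: cramr
Title: Capture-Recapture Animal Models for Partial Seasonal Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of migration versus residence as a
    threshold trait observed through imperfect year-round resighting. Builds
    multi-occasion encounter histories from raw resighting records, computes
    pedigree additive relationship matrices, and fits a capture-recapture
    animal model (CRAM): a hidden-Markov multi-state mark-recapture likelihood
    over resident, two migrant and dead states, whose migration probabilities
    arise from season-specific probit liabilities with additive genetic,
    permanent individual and temporary residual components. Posterior draws
    are obtained by an adaptive Metropolis-within-Gibbs sampler with
    ancillarity-sufficiency interweaving for the variance components. Derived
    liability-scale summaries (heritability, repeatability, individual-variance
    proportion) and an exact functional-ANOVA back-transformation to
    occasion-by-cohort phenotypic variance components are provided, together
    with a synthetic-data generator for calibration and parameter-recovery
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
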