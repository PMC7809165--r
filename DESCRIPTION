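Package: medipath
Title: Microbiome-Mediated Genome Scans via Path Models and Latent-Variable SEM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates direct and microbiome-mediated effects of host genomic
    variants on measured and latent phenotypes. Provides compositional
    preprocessing of OTU count tables (filtering, multiplicative zero
    replacement, centered log-ratio transform), collapsing of cross-classified
    nuisance effects (contemporary group, pen, sire) into standardized linear
    covariates via single-random-effect mixed models, single-feature
    association scans (GWAS, MWAS, genotype-to-microbe), two-equation recursive
    mediation path models with Sobel tests, maximum-likelihood covariance
    structure models for latent fat-deposition factors with latent nuisance
    adjusters, percentile-bootstrap and path-breaking permutation significance
    tests, and an end-to-end discovery pipeline with mediator selection,
    mediation-ratio screening and contiguous SNP window grouping. Includes a
    synthetic-cohort generator with known ground truth for calibration and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    broom,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
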