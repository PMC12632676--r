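Package: nephromr
Title: Proteome-to-Phenome Mendelian Randomization Screening for Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for causal screening of circulating proteins
    against kidney outcomes: synthetic longitudinal cohorts with known causal
    architecture, CKD-EPI eGFR phenotyping with persistence-based case calling
    and mixed-model eGFR slopes, covariate-adjusted per-variant association
    scans, cis-pQTL instrument selection and harmonization, two-sample
    Mendelian randomization (Wald ratio, multiplicative random-effects IVW,
    MR-Egger, Cochran's Q), Cauchy combination (ACAT) aggregation across
    correlated kidney endpoints, Wakefield approximate-Bayes-factor
    colocalization, phenome-wide pleiotropy classification, and drug-target
    evidence networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
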