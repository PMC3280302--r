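Package: longbmi
Title: Longitudinal SNP Association and Joint-Effect Burden Modelling of BMI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal candidate-SNP association analysis of repeated body
    mass index measures in childhood and adulthood strata: linear mixed
    models with a per-subject random effect of age fitted by maximum
    likelihood, additive and general genetic codings combined by a
    minimum-q-value false discovery rate rule, SNP-by-age and
    SNP-by-birth-weight interaction tests, a heuristic forward search for a
    best joint-effect allele-burden model under a per-SNP-penalised modified
    AIC with a permutation empirical p-value, analytic power calculations
    for variance-explained effect sizes, and a synthetic cohort generator
    emulating the design of a longitudinal growth study for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vcfR,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
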