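Package: ideosel
Title: Multi-Trait Ideotype Selection for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for multi-trait, multi-environment plant
    breeding trials: per-trait linear mixed models with REML variance
    components, BLUPs and likelihood-ratio tests; genetic parameters
    (broad-sense and mean-basis heritability, selection accuracy,
    genotype-environment correlation, genotypic and residual coefficients
    of variation); the multi-trait genotype-ideotype distance index
    (MGIDI) with direction-aware rescaling, exploratory factor analysis,
    genotype ranking, selection and selection differentials; and an
    exploratory correlation/PCA layer. Includes a calibrated
    multi-environment trial simulator so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    MASS,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
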