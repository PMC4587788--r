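Package: cagesurv
Title: Direct and Indirect Genetic Effects on Survival of Group-Housed Laying Hens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Variance-component and breeding-value analysis of survival in
    group-housed laying hens where mortality is driven by cannibalism, so that
    an individual's survival depends on its own genes (direct genetic effects)
    and on the genes of its cage mates (indirect, or social, genetic effects).
    Provides a pedigree module (numerator relationship matrix and its sparse
    inverse), a synthetic-population generator with known true effects, design
    builders for four models of survival (a linear model for survival days, two
    repeated-measures random-regression models for monthly 0/1 survival, and a
    logit generalized linear mixed model), an average-information REML engine
    with BLUP and a penalized quasi-likelihood path, cage-level cross-validation
    with censoring-aware ranks and approximate accuracy, and translation of
    monthly variance components and breeding values to the survival-time scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nlme,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
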