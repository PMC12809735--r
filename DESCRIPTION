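Package: hdmixed
Title: Environment-Sensitive Height-Diameter Models for Mixed Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the tree height-diameter allometry of mixed
    forests with stand, site, soil, climate and species-diversity covariates.
    Implements the power-law height-diameter model with covariate-modulated
    scaling exponent, two-stage covariate selection with variance-inflation
    screening, nonlinear least-squares and two-level nonlinear mixed-effects
    estimation (plot and species-within-plot random effects) with
    heteroscedastic variance functions and likelihood-ratio comparison,
    goodness-of-fit and partial R-squared evaluation, allometric-exponent and
    covariate-gradient analyses, and a hierarchical synthetic-forest generator
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    vegan,
    withr
Config/testthat/edition: 3
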