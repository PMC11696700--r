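Package: phytraitsim
Title: Large-Scale Simulation and Model Selection for Continuous Trait
    Evolution on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates continuous trait evolution on rooted phylogenies under
    eleven Brownian-motion-based models expressed as branch-length
    transformations (BM, Ornstein-Uhlenbeck, early burst, Pagel's lambda,
    delta and kappa, linear rate trend, white noise, depth scaling, and local
    clade-rate and time-interval rate shifts), with optional "stacking" of
    local-rate and ancestral mean-shift processes on top of any primary model.
    Supports per-replicate parameter sampling from user-chosen distributions,
    correlated multi-trait simulation via a matrix-normal model, additive
    Gaussian measurement error, and five output formats (raw traits,
    phylogenetic independent contrasts on the input or unit-depth tree, and
    PGLS-whitened traits on either tree). Includes maximum-likelihood fitting
    of the univariate candidate models and bivariate BM/OU/EB, AIC model
    selection with optional measurement-error estimation, and construction of
    confusion matrices summarising model-selection accuracy under graded
    measurement error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
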