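Package: qgstress
Title: Quantitative Genetics of Integrated Behavioural and Endocrine Stress Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the genetic architecture of multivariate
    stress-response phenotypes in pedigreed animal populations. Builds and
    validates additive (numerator) relationship matrices from pedigrees,
    extracts open-field, emergence and shoaling behavioural traits from 2-D
    trajectories (including a random-swim null model that converts raw arena
    coverage into a 'relative area covered' trait), fits univariate, bivariate
    character-state (genotype-by-environment) and multivariate animal models by
    restricted maximum likelihood, and post-processes the resulting additive
    genetic covariance matrix G: genetic correlations, eigen decomposition
    (g-max), parametric-bootstrap confidence intervals and bivariate genetic
    confidence ellipses. A synthetic-study generator reproduces the breeding
    design and assay structure the models assume, so the whole pipeline can be
    exercised and calibrated without access to any particular dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    knitr,
    rmarkdown
Config/testthat/edition: 3
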