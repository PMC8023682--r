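Package: gxeherit
Title: Gene-Environment Interaction Heritability via Randomized
    Haseman-Elston Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the proportion of phenotypic variance explained by
    gene-environment (GxE) interactions from genotype data and multiple
    measured environmental variables, using randomized Haseman-Elston
    (method-of-moments) regression with Hutchinson stochastic trace
    estimation.  Two estimators are provided: a per-environment
    variance-component model (MEMMA) solved analytically, and a non-linear
    least-squares model (GPLEMMA) that jointly estimates a linear
    environmental score and its GxE heritability by a Levenberg-Marquardt
    algorithm with multistart initialization.  Includes PLINK BED/BIM/FAM
    input and output, covariate projection, a pre-screen for squared
    environmental effects, and a simulation framework with known ground
    truth for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
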