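Package: ecrrm
Title: Genomic Prediction with Phenology-Driven Environmental Covariates and
    Random Regression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-environment-trial genomic prediction of grain
    yield using genotype-specific, phenology-driven environmental covariates
    (ECs). Implements a two-stage weighted analysis (per-trial BLUEs with
    Cullis heritability), construction of 45 ECs over vegetative,
    reproductive and grain-filling windows anchored on observed or predicted
    heading dates, partial-least-squares selection of ECs by VIP scores, and
    an average-information REML engine for GBLUP, factor-analytic
    genotype-by-environment, and random-regression reaction-norm models with
    genomic relationship (VanRaden) covariance. Includes CV0/CV1/CV2
    cross-validation harnesses and a synthetic multi-year breeding-program
    generator with a known random-regression truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    mixOmics
Config/testthat/edition: 3
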