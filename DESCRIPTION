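Package: mimicsim
Title: Monte Carlo Evaluation of the MIMIC Model for Uniform DIF Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how well the multiple indicators
    multiple causes (MIMIC) structural equation model detects uniform
    differential item functioning (DIF) in polytomous questionnaire items.
    Generates ordinal item responses from the graded response model with
    normal or standardized-Beta (skewed) latent trait distributions, fits the
    MIMIC model by maximum likelihood with a from-scratch covariance-structure
    optimizer, tests the direct group-to-item path with a Wald statistic, and
    runs factorial Monte Carlo grids to estimate power and Type I error under
    small focal-group sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
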