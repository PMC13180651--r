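Package: worklife
Title: Multistate Working Life Tables from Longitudinal Person-Year Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time incidence-based multistate life tables for working
    life expectancy. Classifies register-style person-year records into five
    labor-market states plus death, estimates gender-stratified multinomial
    logistic transition probabilities with a cubic age polynomial and
    education, and partitions period life expectancy at a baseline age into
    state-specific expectancies by gender and education. Includes a synthetic
    register generator with a fully known ground-truth transition model, a
    Monte-Carlo trajectory oracle, clustered bootstrap intervals, and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
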