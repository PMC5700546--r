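Package: itcfit
Title: Bayesian Global Fitting of Isothermal Titration Calorimetry Binding Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models of single-site and two-site binding-polynomial
    calorimetric titrations with a fraction-competent nuisance parameter,
    global Bayesian estimation of shared thermodynamic parameters across
    replicate experiments with an affine-invariant ensemble MCMC sampler,
    a synthetic-titration generator emulating Cu2+ and Ca2+ binding studies
    of the EF-hand protein S100A5, plain-text integrated-heat I/O, and
    circular-dichroism mean-molar-ellipticity utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
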