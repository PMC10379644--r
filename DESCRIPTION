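Package: listeff
Title: Listening Efficiency from Hierarchical Linear Ballistic Accumulator Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Joint analysis of response accuracy and response time in
    speech-in-noise listening tasks using the linear ballistic accumulator
    (LBA). Provides exact LBA first-passage densities and a race simulator,
    a hierarchical Bayesian estimator with multivariate-normal individual
    parameters and chance-level treatment of deadline-censored trials,
    differential drift rates ("listening efficiency") with condition
    contrasts, highest-density intervals and Cliff's delta effect sizes,
    plausible-values correlations with an exact population-correlation
    posterior, LMG relative-importance decomposition, ordered beta
    regression for bounded visual-analog ratings, and a synthetic-data
    generator emulating a two-group (cochlear implant vs normal hearing)
    speech-in-noise study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
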