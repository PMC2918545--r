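Package: gamscan
Title: GAM Permutation Tests and the Bernoulli Spatial Scan Statistic for
    Case-Control Point Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection of spatial variation in disease risk from case-control
    point data.  Fits logistic generalized additive models with a bivariate
    LOESS smoother of geographic location by local scoring, and tests the
    global null hypothesis of no spatial variation with four permutation
    tests of the difference-in-deviance statistic (conditional, fixed-span,
    fixed-multiple-span and unconditional).  Point-wise permutation
    distributions of predicted log odds locate hotspots and coldspots.  Also
    implements the circular Bernoulli spatial scan statistic with Monte
    Carlo inference, three synthetic disease-risk scenario generators
    (circular cluster, radial point source, vertical line source),
    closed-form theoretical power for the matching non-spatial reference
    tests, and a simulation harness for type I error, power and
    source-detection sensitivity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
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
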