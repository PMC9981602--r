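Package: parastage
Title: Stage-Structured Analysis of Parasitoid Efficacy on Hosts Raised
    Along a Food-Quality Gradient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for stage- and age-structured analysis of idiobiont
    parasitoid efficacy on seed-beetle hosts reared on a resource-quality
    gradient.  Includes a synthetic exposure-experiment generator with
    quality-dependent host development, age-by-stage probability tables
    and multiple imputation of unobserved host stages, Cox
    proportional-hazards estimation of daily parasitism risk with Efron
    or Breslow handling of tied event times, imputation-bootstrap and
    treatment-permutation null distributions with percentile p-values,
    and an AIC/qAIC model-selection suite of generalized linear and
    penalized-spline additive models with factor-by smooths, post-hoc
    contrasts and pairwise smooth comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    splines,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    mgcv,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
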