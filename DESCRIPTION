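Package: lesionbem
Title: Boundary-Element Head Modelling and Stroke Lesion Conductivity
    Estimation for Transcranial Electric Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nested-compartment boundary-element forward modelling of scalp
    potentials generated by transcranial electric stimulation, and estimation
    of the electrical conductivity of a chronic stroke lesion from those
    potentials. Provides synthetic multi-shell spherical head models with
    spherical lesion inclusions, a closed-form layered-sphere oracle for
    solver validation, exhaustive search for the stimulation electrode pair
    most sensitive to the lesion, simulation of electrode coregistration
    error by rigid rotation of the measurement montage, a seeded multi-start
    damped Gauss-Newton conductivity estimator, and a study runner sweeping
    lesion size, lesion conductivity, rotation angle and electrode count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
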