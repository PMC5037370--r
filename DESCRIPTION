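Package: microtissue
Title: Viscoplastic Modeling of Active Microtissue Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and parameter estimation for a three-element
    constitutive model of engineered smooth-muscle microtissues: a Hill-type
    active contractile element in series with a linear spring, acting in
    parallel with an elastic perfectly viscoplastic (Bingham-Norton)
    extracellular-matrix element. Includes reduced model variants for
    cell-lysed (matrix-only) tissues and single cells on micropost arrays,
    generators for stretch-unstretch-observe loading protocols, conversion of
    microcantilever and micropost deflections to forces and stresses, a
    random-search least-squares fitting procedure with identifiability
    profiling, and synthetic-experiment generators so the full analysis
    pipeline can be exercised end to end without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
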