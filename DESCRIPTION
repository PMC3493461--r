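Package: stringnet
Title: Topology and Parameter Inference of Elastic String Networks by
    Estimation-Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the functional structure (topology and parameters) of
    tension-only elastic string networks, such as string approximations of the
    finger extensor mechanism, from sparse tensile tests.  Provides a
    geometrically and materially nonlinear truss statics solver (slack/taut
    elements, Newton-Raphson equilibrium), fitness metrics for model-data
    agreement and inter-model disagreement, a random-mutation hill climber
    that co-evolves a population of candidate networks against maximally
    informative force tests, and a virtual laboratory that emulates the
    dynamometer/caliper measurement protocol on known in-silico targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
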