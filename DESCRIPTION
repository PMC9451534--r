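Package: statearray
Title: State Arrays and Dirichlet Process Mixtures for Single-Particle
    Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers distributions of diffusing-state parameters
    (diffusion coefficient, localization-error variance, optionally the
    Hurst parameter) from large collections of short single-particle
    tracking trajectories.  Implements variational inference over a fixed
    grid of candidate states ("state arrays"), a Dirichlet-process
    mixture Gibbs sampler on the marginal jump-variance parameter, a
    defocalization bias correction based on iterated
    convolution-transmission propagation of the axial density, and a
    stroboscopic trajectory simulator with sphere confinement, focal-slab
    observation, photobleaching and sub-frame state switching for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
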