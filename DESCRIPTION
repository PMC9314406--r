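Package: binodev
Title: Development of Binocular Congruence in a Model of Primary Visual
    Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the development of binocular congruence in the
    geniculocortical pathway of the cat. Jittered mosaics of on- and
    off-centre subcortical channels from the two eyes drive a four-stage
    linear-nonlinear cascade (cones, bipolar cells, ganglion cells,
    geniculate relay cells) converging onto excitatory and two-compartment
    inhibitory cortical neurons. Geniculocortical synapses develop by
    Hebbian plasticity in two phases: monocular drifting-wave stimulation
    before eye opening, then binocular stimulation with fixation offsets.
    Includes a fast periodic steady-state solver cross-checked against
    time-domain integration, and analysis tools for receptive-field
    mapping, orientation tuning (von Mises fits), binocular disparity
    tuning, ocular dominance, circular map statistics and map periodicity.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
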