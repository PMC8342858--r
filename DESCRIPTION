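Package: neuropilsim
Title: Monte Carlo Simulation of Glutamate Diffusion and Transporter
    Capture in Sphere-Packed Neuropil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Brownian-dynamics Monte Carlo simulation of neurotransmitter
    diffusion in a synthetic brain neuropil built from randomly sized,
    overlapping spheres. Particles released at a synaptic cleft diffuse
    through the interstitial gaps, collide elastically with obstacle
    surfaces, and can be captured permanently within a thin catchment
    layer representing high-affinity glial glutamate transporters. The
    package generates porous media at a target occupied volume fraction,
    propagates particle ensembles with a tunnelling-safe time step,
    fits Gaussian dispersions to spatial scatter histograms, measures
    capture-distance statistics and effective diffusion coefficients,
    and ships named scenario presets for standard neuropil conditions
    (cerebellar and hippocampal astroglial coverage, shrunken and
    expanded extracellular space).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
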