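Package: leafeb
Title: Dynamic Leaf Energy Balance and Stomatal Conductance Kinetics from
    Thermography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts leaf temperature kinetics under fluctuating
    environments from the kinetics of a reference material using a
    dynamic (reference-differenced) energy-balance model, and inverts the
    model by Bayesian inference to recover the temporal response of
    stomatal conductance, the boundary-layer conductance and leaf
    thermal/optical properties from thermography time series.  Includes
    psychrometric property functions, smoothing-spline signal models, a
    Gompertz-type stomatal kinetics model for dark/light/dark protocols,
    boundary-layer estimation from a black/white reference pair, pore
    diffusion conductance for perforated leaf replicas, a forward
    simulator for complete synthetic experiments, and MCMC fitting with
    rank-normalised split-Rhat and effective-sample-size diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
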