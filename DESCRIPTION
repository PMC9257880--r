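Package: cpgait
Title: Compass-Gait Walker with a Phase-Resetting Central Pattern Generator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a planar compass-type bipedal walker driven by a
    phase-oscillator central pattern generator (CPG) under stochastic joint
    torque noise, and quantifies the statistical persistence of stride-interval
    fluctuations by detrended fluctuation analysis (DFA).  The CPG couples to
    the mechanics either through phase resetting at foot contact or through a
    passive half-period phase flip; the package provides the hybrid
    (continuous/impact) dynamics, Euler-Maruyama trial simulation, noiseless
    limit-cycle and Floquet analysis, phase-response-curve sampling,
    energy-optimal gait parameter calibration by grid search, DFA with
    surrogate shuffling, and generators of reference time series (white,
    brown, fractional Gaussian noise) of known scaling exponent.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
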