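Package: condrob
Title: Conditional Robustness Analysis for Dynamical Biochemical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Moment-independent, sampling-based conditional robustness
    analysis for parametric dynamical models of biochemical networks.
    Latin hypercube sampling of a multiplicatively bounded parameter
    space is combined with numerical ODE simulation, partitioning of an
    evaluation function's sample distribution into extreme lower and
    upper tails, Gaussian kernel conditional density estimation, and a
    moment-independent robustness indicator (the L1 distance between
    tail-conditioned parameter densities) to rank parameters and select
    a small conditioning set that shifts the output density toward a
    desired regime. Ships a two-state incoherent-feedforward pulse
    generator and a ten-state EGFR-IGF1R signalling cascade as built-in
    models, plus closed-form fixture models for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    lhs,
    jsonlite,
    pracma,
    stats,
    utils,
    parallel,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
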