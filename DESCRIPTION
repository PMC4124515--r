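Package: neurofrag
Title: Conservative Fragmentation Dynamics of Elapsed-Time Neural Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator and spectral-analysis toolkit for a conservative
    nonlinear fragmentation equation structured by the time elapsed since a
    neuron's last discharge. Provides validated model coefficients (firing
    rate families with activity-dependent refractory thresholds,
    fragmentation kernels with contraction bounds), a mass-conservative
    transport-discharge-redistribution time stepper with a per-step implicit
    solve of the total network activity, truncated eigenproblem solvers for
    the stationary density and its nonlinear fixed point, construction of
    the dual weight certifying exponential relaxation, and diagnostics that
    classify long-time regimes (desynchronization versus periodic network
    activity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
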