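Package: simulfit
Title: Simultaneous Curve Fitting of Expressions and Differential
    Equations with Shared Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global (simultaneous) nonlinear least-squares fitting across
    many datasets.  Models are defined as closed-form expressions or as
    systems of ordinary differential equations; parameters can be shared
    across datasets and models through an explicit fit topology
    (model-shared, per-dataset, detached, or constant).  Bound constraints
    are enforced by smooth parameter transforms so that optimization runs
    on an unconstrained hidden vector, and gradients are computed
    analytically (symbolic differentiation for expression models, forward
    sensitivity equations for ODE models) for use with L-BFGS, with
    Nelder-Mead as a gradient-free fallback.  Includes a stochastic
    logistic-growth data generator for examples and tests, CSV/TSV data
    input, a YAML fit-configuration format, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
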