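Package: vesikin
Title: Release-Site Kinetics of Synchronous and Asynchronous
    Neurotransmitter Release
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a dual calcium-sensor model of synaptic vesicle
    release in which release sites cycle between empty, tethered and
    docked states, fusion is gated by calcium binding to synaptotagmin-1
    and Doc2alpha under a shared five-ion budget, and synaptotagmin-7
    catalyzes docking and undocking. Provides the action-potential-driven
    calcium transient, intensity-matrix construction, steady states by
    null-space and matrix-exponential routes, stiff ODE integration,
    a single-site stochastic (thinning) simulator, genotype knockouts,
    one-at-a-time parameter sweeps, and quantification of optical
    glutamate-sensor traces and evoked-current trains (event detection,
    asynchronous-release fractions, paired-pulse ratio, cumulative-charge
    decomposition, tonic charge), together with synthetic-data generators
    with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
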