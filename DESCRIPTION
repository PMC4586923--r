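Package: dicurves
Title: Dynamic Input Conductance Analysis of Conductance-Based Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes the excitability of an arbitrary conductance-based
    neuron model into three voltage-dependent dynamic input conductances
    (fast, slow, ultraslow) that aggregate the contribution of every ion
    channel in each timescale of the firing pattern. Provides the analytic
    timescale decomposition, a simulated voltage-clamp protocol that measures
    the same curves from current transients, per-channel sensitivity curves
    of each dynamic input conductance with respect to maximal conductances,
    spike-threshold and up-state voltage markers, and the linear compensation
    mechanism that co-varies potassium conductances and applied current to
    preserve firing when a calcium channel density is perturbed. Ships a
    six-current stomatogastric-ganglion (STG) burster model, the classical
    Hodgkin-Huxley model, and analytic toy models as fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
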