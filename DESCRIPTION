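Package: acnet
Title: Auditory Cortex as a Dynamical Network of Damped Oscillators
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the serially connected core-belt-parabelt network of
    auditory cortex as coupled excitatory/inhibitory neural-mass populations
    whose excitatory synapses undergo short-term synaptic depression (STSD).
    Provides the normal-mode (eigendecomposition) solution of the linearised
    system, a slow-fast scheme that carries the synaptic efficacy as a
    piecewise-constant state across a periodic stimulus train, a forward model
    for the magnetoencephalographic event-related field (ERF) with per-mode and
    per-connection decompositions, and tools to quantify ERF adaptation:
    saturating-exponential recovery fits of peak amplitude versus stimulus
    onset interval, and the local saturation rate diagnostic.  A reference
    numerical integrator of the full nonlinear system is included for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
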