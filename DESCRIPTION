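Package: phasereset
Title: Phase-Resetting Maps for Cardiac Oscillators and Modulated Parasystole
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing entrainment of spontaneously beating cardiac
    oscillators through phase response curves (PRCs). Provides parametric PRC
    families with a triggering discontinuity, least-squares PRC fitting from
    stimulus-phase measurements, the one-dimensional phase map for a
    periodically forced oscillator with orbit and bifurcation analysis, a
    modulated-parasystole model with conduction delay and refractory blocking
    (phase map and event-level beat simulator), inference of model parameters
    from timestamped beat annotations (sinus period, resetting slope,
    refractory function, grid/MAE fitting, Kolmogorov-Smirnov segment
    scoring), locking-zone and PVC-burden parameter sweeps, PRC construction
    from a simulated limit-cycle oscillator, and synthetic-data generators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
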