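Package: mirsalt
Title: Salt-Responsive miR165/166-PHB-Cytokinin Feedforward Loop Model
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deterministic ODE model of how salt stress modulates the
    incoherent feedforward loop linking miR165/166, the HD-ZIPIII
    transcription factor PHABULOSA (PHB) and cytokinin in the Arabidopsis
    root meristem. Provides steady-state solvers with salt-gradient
    continuation sweeps, adaptive Runge-Kutta time-course integration under
    piecewise-constant salt forcing, in-silico simulation of the phb-1d
    gain-of-function mutant, a synthetic qRT-PCR fold-change (2^-ddCt) data
    generator, least-squares parameter inference on log2 fold changes, and a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
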