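Package: erpdistract
Title: Auditory-Visual Distraction ERP Analysis with Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of event-related potentials (ERPs) from
    an auditory-visual distraction paradigm. Generates multichannel EEG with
    embedded mismatch negativity (MMN), early and late P3a, and reorienting
    negativity (RON) components plus behavioral reaction times; implements the
    full measurement chain (ocular regression, epoching, zero-phase band-pass
    filtering, baseline correction, artifact rejection, difference waveforms,
    window-constrained peak measurement), spherical-spline current source
    density and voltage topographies, and mixed-design ANOVAs with
    Greenhouse-Geisser correction, Bonferroni post-hoc comparisons, partial
    eta squared, and Cohen's d.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: signal, jsonlite, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
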