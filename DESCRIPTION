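Package: pswer
Title: Detection and Analysis of Paroxysmal Slow-Wave Events in Resting-State EEG
Version: 0.1.0
Authors@R:
    person("pswer", "developers", email = "pswer@example.org", role = c("aut", "cre"))
Description: Tools to quantify transient cortical slowing in multi-channel
    resting-state EEG. Implements the paroxysmal slow-wave event (PSWE)
    pipeline: FIR band-pass/band-stop preprocessing with average
    re-referencing, spatial averaging of 10-10 electrodes into nine
    anatomical areas, sliding-window FFT spectra with median power
    frequency (MPF) time-courses, run-length event detection (MPF below a
    threshold for a minimum duration), relative band-power tables,
    threshold sweeps, and cohort-level nonparametric statistics. Includes
    a synthetic EEG cohort generator with planted slow-wave ground truth,
    a minimal EDF reader/writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
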