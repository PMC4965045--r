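Package: fnirsbci
Title: Real-Time fNIRS Brain-Computer Interface Simulation and Classification
Version: 0.1.0
Authors@R:
    person("BCI", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a real-time functional
    near-infrared spectroscopy (fNIRS) brain-computer interface for left
    versus right hand motor execution and motor imagery. Provides a
    checkerboard optode montage and block-design protocol model, a
    synthetic multi-channel oxy-/deoxy-hemoglobin generator with
    task-locked hemodynamic responses, offline preprocessing (baseline
    correction, hemodynamic pre-coloring, wavelet-MDL detrending),
    per-second feature extraction, Parzen-window mutual-information
    channel selection, an adaptively retrained linear support-vector
    machine with rest-block bias correction, a streaming session loop
    with thermometer neurofeedback, ROC and cross-validation evaluation,
    and plain-text readers/writers plus a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
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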