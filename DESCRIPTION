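Package: nirsconn
Title: Resting-State Functional Connectivity and Network Analysis for fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolchain for resting-state functional near-infrared
    spectroscopy (fNIRS): reading .nirs and Hitachi-style CSV recordings,
    conversion of raw optical intensity to optical density and hemoglobin
    concentration changes via the modified Beer-Lambert law, zero-phase
    Butterworth band-pass filtering, linear detrending, motion-artifact
    correction (moving-standard-deviation detection with spline subtraction,
    and correlation-based signal improvement), channel quality control
    (SNR and whole-brain correlation checks), seed-based and whole-brain
    functional connectivity with Fisher r-to-z group statistics, and
    graph-theoretical network metrics (small-world coefficients, efficiencies,
    modularity, hierarchy, nodal degree/efficiency/betweenness) normalized
    against degree-preserving random null networks. A synthetic-data module
    generates multichannel recordings with known block connectivity, injected
    motion artifacts, and low-SNR channels so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    yaml,
    parallel,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
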