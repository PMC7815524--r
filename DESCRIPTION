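Package: fieldlab
Title: Analysis and Simulation of Extracellular Field-Potential Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing hippocampal slice field-potential
    electrophysiology: input-output curves, fiber volley amplitude, fEPSP
    initial slope, paired-pulse ratio, theta-burst LTP magnitude,
    tetanus-depolarization area under the curve, and a modified Coastline
    Burst Index, together with a seeded generative simulator of
    extracellular sweeps, Welch group comparisons with Grubbs outlier
    screening, and an end-to-end cohort pipeline with reproducible seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
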