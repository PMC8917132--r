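Package: rippletiming
Title: Pre-Ripple Inhibition and Spike Timing Analysis for Hippocampal
    Sharp-Wave Ripples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing how inhibition preceding
    hippocampal sharp-wave ripples (SWRs) shapes the spike and
    depolarization timing of CA1 pyramidal cells. Implements SWR
    detection from band-passed local field potentials (threshold and
    normalized-squared-signal detectors), intracellular membrane
    potential analysis (spike truncation, pre-ripple hyperpolarization
    quantification, depolarization peak timing, synaptic conductance
    decomposition), quintile/shuffle tests linking interneuron pre-SWR
    firing to pyramidal first-spike latency, a Poisson-emission hidden
    Markov model for SWR spike sequences with cross-quintile likelihood
    comparison, and a Poisson mixture model for interneuron ensemble
    detection with cross-validated deviance and curvature-based model
    selection. Ships seeded synthetic-data generators for every input so
    the full pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
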