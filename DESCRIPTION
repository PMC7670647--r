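Package: rifttag
Title: Simulation and Analysis of Rapid Invisible Frequency Tagging Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates broadband phase-modulated (60-70 Hz) luminance tagging
    signals, simulates MEG-like multichannel recordings of a covert
    spatial-attention task (lateralized alpha oscillations, attention-gain
    scaled tagging responses with a fixed sensor latency, 1/f background
    noise, eye and photodiode channels, artifacts, and a QUEST-driven
    behavioral observer), and analyses them: epoching and artifact rejection,
    band power and the attention modulation index (AMI), trial median-split
    independence analysis, cross phase-locking value (cross-PLV) latency
    estimation with circular-shift surrogate confidence bounds, and
    group-level paired tests and rank correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
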