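Package: fnirsbci
Title: Online fNIRS Passive Brain-Computer Interface for Working-Memory Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating an online passive
    brain-computer interface from prefrontal functional near-infrared
    spectroscopy (fNIRS) recordings. Converts raw two-wavelength optical
    intensities to oxy-/deoxy-hemoglobin concentration changes via the
    modified Beer-Lambert law, band-pass filters each channel in real time
    with a causal MACD (difference-of-exponential-moving-averages) filter,
    segments the stream into task-locked trials, and classifies single-trial
    working-memory load with a per-subject linear support vector machine
    whose regularization is selected by cross-validation. Includes a
    synthetic fNIRS session generator with known ground truth, offline
    statistics (peak responses, region-of-interest averaging, effect sizes,
    exact binomial chance thresholds), and CSV/YAML interfaces for streams,
    trial events and device profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
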