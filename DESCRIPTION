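Package: carbonpath
Title: Operational Carbon Footprint of Deep Learning in Digital Pathology
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the operational greenhouse-gas emissions of deep-learning
    inference in digital pathology. Generates synthetic whole-slide-image
    cohorts with realistic tile workloads, normalises per-model energy to a
    reference workload of 1e7 tiles, calibrates a log-log parameter-energy
    scaling law with bootstrap uncertainty, converts energy to CO2-equivalents
    through grid carbon intensity, expresses emissions as tree and forest
    sequestration equivalents, extrapolates institute-level results to
    national and global scale through cancer-case anchors, and projects
    emissions to 2052 under renewable-energy, model-complexity,
    hardware-efficiency and case-count drivers with bootstrap bands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
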