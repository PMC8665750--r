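Package: eicpeaks
Title: Targeted Peak Extraction and Integration for LC-MS Profiling Data
Version: 0.1.0
Authors@R:
    person("Phenome", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Targeted extraction and integration of annotated chemical
    compounds from liquid chromatography-mass spectrometry (LC-MS) profiling
    runs. Reads mzML raw data, extracts ion chromatograms over user-supplied
    retention-time x m/z regions of interest (ROI), fits chromatographic
    line-shape models (Gaussian, skew-normal-scaled Gaussian, exponentially
    modified Gaussian) with a trapezoidal fallback integration for aberrant
    shapes, aggregates results across a dataset, proposes consensus-refined
    integration windows for a second pass, and re-calibrates retention time
    from calibrant compounds with a RANSAC-robust fit. Ships a synthetic-run
    generator with a full ground-truth ledger so every stage is testable
    without external data, and a command-line interface for batch workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    parallel,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
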