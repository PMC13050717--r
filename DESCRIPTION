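Package: tadcal
Title: Calcium-Imaging and Locomotor Phenotyping of Tadpole Epilepsy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for widefield GCaMP calcium imaging and
    locomotor tracking of Xenopus tadpole seizure models. Converts
    fluorescence movies to dF/F0 stacks, detects calcium events on
    high-pass-filtered whole-brain traces against a pooled-control 3-SD
    threshold, computes low-frequency power spectral densities on a common
    0.01-1 Hz grid, measures interhemispheric synchrony from fixed-area
    centroid regions of interest, and summarises swim velocity and darting
    behaviour from high-speed trajectories. Includes a calibrated synthetic
    generator that emulates control, CRISPant, and drug-treated cohorts with
    recoverable ground truth, plus the group statistics used for cohort
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tiff,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
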