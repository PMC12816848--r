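Package: twomapper
Title: Threshold-Weighted Overlap Mapping for Task fMRI Consistency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies inter-subject and test-retest consistency of task fMRI
    activation across cohorts of co-registered, unthresholded z-statistic
    volumes using threshold-weighted overlap mapping (TWOM). Each voxel's
    consistency is the weighted area under the curve of the fraction of
    subjects activating across a sweep of statistical thresholds, yielding
    values in [0, 1]. Includes relevant-voxel selection heuristics,
    spherical neighbourhood sampling tolerant to small anatomical
    misalignment, engagement-proportion maps, per-voxel activation profiles
    with atypical-subject flagging, cluster/peak tables, Dice similarity of
    activation masks, fixed-effects group combination, a minimal block-design
    first-level GLM, and a seeded synthetic-cohort generator (direct z-map
    and BOLD time-series modes) with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
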