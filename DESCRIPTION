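Package: ippg
Title: Imaging Photoplethysmography of Meningeal Blood Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for camera-based (imaging photoplethysmography, iPPG)
    assessment of meningeal blood flow through a closed cranial window.
    Provides a synthetic-data generator with known ground truth (cranial
    window video, ECG, arterial pressure and experiment schedules),
    segment-wise gradient-based motion compensation, cardiac-gated
    extraction of the pulsatile amplitude (APC) and optical intrinsic
    signal (OIS) maps, stimulation-response integral metrics with
    baseline normalization, and the rank-based statistical design
    (Wilcoxon signed-rank, Friedman, Kruskal-Wallis with Bonferroni
    post-hoc correction) used for cumulative-infusion pharmacology
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    pracma,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'geometry.R'
    'kinetics.R'
    'tissue.R'
    'simulate-trial.R'
    'simulate-experiment.R'
    'motion.R'
    'ppg.R'
    'ois.R'
    'response.R'
    'stats.R'
    'pipeline.R'
    'io.R'
    'plots.R'
    'ippg-package.R'
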