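Package: cardiogate
Title: Prospective Optical Gating and Functional Quantification for the
    Embryonic Zebrafish Heart
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for laser-cardiac-cycle synchronization and quantitative
    phenotyping of the beating embryonic zebrafish heart from video
    microscopy. Implements prospective optical gating (image-similarity
    cardiac phase estimation, linear phase-rate prediction and
    latency-compensated trigger emission), area-based heart rate, ejection
    fraction and ventricle diastolic area measurement, caudal-vein
    erythrocyte particle-tracking velocimetry, 3-D counting of total and
    mitotic ventricular cardiomyocyte nuclei and of TUNEL puncta in
    confocal z-stacks, and group-level summary statistics with Bonferroni
    post-hoc comparisons. A synthetic-data module renders beating-heart
    videos, vessel videos and immunostained z-stacks with known ground
    truth so every pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    pracma,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: CellBiology, Visualization
RoxygenNote: 7.3.3
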