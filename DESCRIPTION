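Package: follicleQuant
Title: Quantification of Epithelial Cytokinesis Failure in the Drosophila Follicular Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification pipeline for scoring cytokinesis efficiency in
    curved epithelial monolayers such as the Drosophila follicular epithelium.
    Provides a curvature-aware, nucleus-anchored local z-projection of two-channel
    3D stacks, central-ROI cell and nucleus segmentation with nuclei-per-cell
    counting, the delta-multinucleation modifier statistic used in RNAi screens,
    cytokinetic-ring constriction-rate estimation from diameter traces,
    ROI-based cortical fluorescence quantification with cytoplasmic background
    subtraction, and three-category cytokinesis-failure scoring of time-lapse
    event logs. A synthetic-data generator with full ground truth (tissue stacks,
    constriction traces, intensity scenes, event logs) makes every stage testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
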