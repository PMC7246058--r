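Package: lungseg
Title: U-Net Semantic Segmentation of Lungs Excluding the Trachea and Main
    Bronchi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating normal lung on thoracic CT while excluding
    the trachea and main bronchi, the organ-at-risk definition used in lung
    radiotherapy planning. Provides synthetic thorax phantoms with ground
    truth, DICOM CT / RT Structure Set reading and contour rasterization,
    PNG mask-stack input/output, 2D and 3D U-Net encoder-decoder networks
    trained with a composite Jaccard+Dice overlap loss, flip and intensity
    inversion augmentation, 5-fold cross-validation with per-voxel
    majority-vote ensembling, and Dice-based cohort comparison by the
    Wilcoxon signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
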