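Package: fmfangle
Title: Automated Frontomaxillary Facial Angle Measurement from Fetal Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage automatic measurement of the fetal frontomaxillary
    facial (FMF) angle from 2D mid-sagittal ultrasound images: semantic
    segmentation of the palate and frontal bone with an atrous-spatial-
    pyramid-pooling network, landmark localisation by Gaussian heatmap
    regression with a two-branch high-resolution network, and angle
    computation from the three landmarks by the law of cosines. Includes a
    synthetic phantom simulator with exact ground truth, readers/writers for
    Labelme polygon and COCO keypoint annotations, segmentation metrics
    (pixel accuracy, IoU, Dice), paired-measurement agreement statistics
    (MAE, MRE, Pearson, ICC(2,1), Bland-Altman limits of agreement), and a
    reproducible end-to-end pipeline driver. Networks are trained with a
    compact built-in CNN engine (im2col + BLAS via 'RcppArmadillo').
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
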