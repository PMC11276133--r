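Package: pvscade
Title: Cascaded Enhancement and Counting of Enlarged Perivascular Spaces on T2 MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing enlarged perivascular spaces (ePVS) in the
    basal ganglia on T2-weighted MRI with a two-stage cascade: a U-Net style
    image-to-image regression network that selectively brightens ePVS, followed
    by a convolutional count-regression network that predicts the number of
    ePVS per image. Includes a seeded synthetic phantom generator (grade-skewed
    puncta on textured tissue), classical enhancement baselines (white top-hat,
    CLAHE, Laplacian sharpening), and the full evaluation protocol:
    contrast-to-noise ratio, Potter 0-4 grading, subject-level max aggregation,
    MAE/MSE, grade accuracy, ICC(2,1) with confidence interval, and
    subject-level 4-fold cross-validation. Neural-network training is
    implemented natively (RcppArmadillo) with Adam, batch normalization and
    geometric augmentation, so the whole cascade runs on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
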