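Package: gasfeeg
Title: Image-Based Epilepsy Detection from EEG via Gramian Angular Summation Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects focal (epileptogenic) versus normal EEG by encoding
    fixed-length signal epochs as Gramian Angular Summation Field (GASF)
    images, extracting SIFT or ORB keypoint descriptors from the images,
    summarising each image as a bag-of-visual-words histogram over a
    k-means vocabulary, ranking histogram features by a chi-square score
    against the class labels, and classifying with RBF-kernel support
    vector machines, random forests, or k-nearest neighbours. Includes a
    two-class synthetic EEG generator, Gaussian-noise injection at a
    requested signal-to-noise ratio, a noise-robustness sweep over an SNR
    grid, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
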