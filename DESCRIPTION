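Package: stomadetect
Title: Stomata Classification and Detection in Maize Microscope Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic classification and detection of stomata in microscope
    images of maize leaf epidermis. Implements five handcrafted window
    descriptors (HOG, DAISY, LBP, GLCM/Haralick, GIST), linear SVM, MLP and
    AdaBoost classifiers benchmarked under image-level k-fold
    cross-validation, and a sliding-window detector that merges positive
    windows through a per-pixel occurrence matrix into detected stoma
    regions scored against ground-truth counts. Includes a synthetic
    epidermis-image generator with exact ground truth and configurable
    imaging artifacts so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    nnet,
    jsonlite,
    png,
    tiff,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
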