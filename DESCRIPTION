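Package: bonetex
Title: Trabecular Bone Texture Classification from Knee Radiograph Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture-based classification of trabecular bone patches cut from
    high-resolution knee radiographs, aimed at detecting early osteoarthritis
    when sample sizes are small. Implements Zernike orthogonal moments (real
    parts up to order 16, 81 features) and the 14 Haralick gray-level
    co-occurrence statistics as texture descriptors; a two-sample
    Kolmogorov-Smirnov minimum-distance baseline classifier with a rejection
    rule on pooled pixel-brightness distributions; and a GMDH-type (Group
    Method of Data Handling) polynomial neural network grown layer by layer
    under an external held-out selection criterion, with feature-importance
    reporting. Evaluation uses leave-one-out cross-validation. A synthetic
    Gaussian-random-field texture generator provides two-class fixtures with
    controllable brightness statistics and spatial correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    randomForest,
    e1071,
    nnet,
    optparse,
    jsonlite
Config/testthat/edition: 3
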