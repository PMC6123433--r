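Package: nucleomorph
Title: Nuclear Morphometry and Weakly Supervised Deep Learning for H&E
    Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts a binary molecular label (clinical estrogen-receptor
    status) from hematoxylin-and-eosin histology using interpretable,
    pre-defined nuclear features. The pipeline segments nuclei with
    classical operators (Otsu and local adaptive thresholds, watershed),
    measures per-nucleus morphometry (axes, area, perimeter, circularity,
    orientation), encodes nuclei as sparse 12-channel feature images with
    one-hot 30-degree orientation bins, trains a small fully convolutional
    network on weakly labeled patches with dihedral augmentation realised
    as channel permutation, and interrogates the trained model through
    digital staining, ranked patch-group morphometry and a logistic
    regression baseline. Includes a seeded synthetic tissue generator
    (clustered nuclei point fields and rendered H&E-like images) so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    EBImage,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    glmnet,
    png,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
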