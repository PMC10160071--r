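Package: ramantda
Title: Topological Machine Learning for Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of Raman spectra of chondrogenic bone tumours
    (enchondroma and chondrosarcoma grades G1-G3) with topological features.
    Spectra are embedded as planar point clouds, summarised by Vietoris-Rips
    persistent homology in dimensions 0 and 1, vectorized with persistence
    images, landscapes, silhouettes and Betti curves, and fed to a classifier
    grid search under patient-aware (leave-one-patient-out) validation.
    Includes a class-structured synthetic spectrum generator with patient-level
    effects, a five-transform augmentation scheme, a no-topology ablation and
    an unsupervised clustering evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    mclust,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
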