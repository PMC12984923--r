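Package: entrosel
Title: Entropy-Based Texture Features with Metaheuristic Wrapper Feature
    Selection for MRI Region Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements an optimization-driven pipeline for classifying
    tumor versus non-tumor regions of interest in grayscale MRI patches.
    Image patches are denoised, resized and rasterized into 1-D intensity
    signals from which a bank of 39 entropy-based descriptors (approximate,
    sample, fuzzy, permutation, dispersion, spectral and further single- and
    cross-signal measures) is computed. A wrapper feature selector driven by
    the superb fairy-wren optimization algorithm (with particle swarm,
    Harris hawks and puma optimizer baselines) searches the binary feature
    space against a k-nearest-neighbor fitness, and final models are
    evaluated with stratified cross-validation, confusion-matrix metrics and
    ROC/AUC. A synthetic data generator with planted class structure makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    e1071,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    class,
    kernlab,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
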