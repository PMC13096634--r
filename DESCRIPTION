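Package: aohho
Title: Hybrid Aquila-Harris Hawks Optimization for CNN Hyperparameter Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tunes convolutional neural network hyperparameters with a hybrid
    metaheuristic that runs Aquila Optimizer (AO) global exploration in early
    iterations and Harris Hawks Optimization (HHO) local exploitation
    afterwards. Includes the four AO position-update strategies with
    Mantegna Levy flights, the HHO escape-energy besiege modes, a mixed
    continuous/categorical search-space codec, a compact CNN engine
    (two convolutional blocks, dense head, Adam/SGD) written in C++ for
    4-class 64x64 grayscale image classification, a composite
    loss-plus-training-cost objective, a reproducible synthetic brain-MRI-like
    dataset generator with standard augmentation, benchmark test functions,
    and a five-run statistical validation harness (mean +/- SD tables and
    paired t-tests with confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    EBImage,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
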