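Package: wpemg
Title: Wavelet-Packet Features and Ensemble Classification for EMG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for automated classification of single-channel
    electromyography (EMG) recordings into Normal, Myopathy and Neuropathy
    classes. Implements a synthetic motor-unit action potential (MUAP) train
    simulator, fixed-length rectangular framing, a level-4 wavelet packet
    decomposition with six per-subband statistical features, native base
    learners (gain-ratio decision tree, Gaussian naive Bayes, k-nearest
    neighbours, random tree, random forest), the bagging, AdaBoost.M1 and
    MultiBoosting committee meta-algorithms, and stratified k-fold
    cross-validation with accuracy, precision/recall/F, one-vs-rest AUC and
    Cohen's kappa reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    foreign,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
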