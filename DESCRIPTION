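Package: ecgsqa
Title: Featureless Quality Assessment of Single-Lead ECG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies 5-second single-lead ECG segments as high or low
    quality without fiducial-point feature extraction. Segments are turned
    into continuous-wavelet-transform (Morlet) scalogram images and scored
    by an AlexNet-architecture convolutional network fine-tuned for the
    two-class problem; a classical baseline combining four signal quality
    indices (bSQI, pSQI, kSQI, basSQI) through a Gaussian-kernel support
    vector machine is provided for comparison, together with the
    class-rebalanced stratified multi-cycle validation protocol used to
    evaluate both classifiers and a synthetic single-lead ECG generator
    (NSR, AF and other rhythms; motion artifact, powerline, baseline
    wander and EMG noise at controlled SNR) so the full pipeline runs
    without any recording downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    signal,
    e1071,
    EBImage,
    png,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
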