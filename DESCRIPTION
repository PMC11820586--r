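Package: r2wnet
Title: Fetal ECG Extraction with a W-Shaped Recurrent-Residual Attention Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates fetal and maternal electrocardiograms from single-channel
    maternal abdominal recordings. Provides a synthetic abdominal-ECG generator
    with ground-truth components and R-peak annotations, the standard
    conditioning chain (band-pass filtering, resampling to 250 Hz, overlapped
    1024-sample windowing, per-window Z-score normalisation), a dual
    encoder-decoder ("W"-shaped) neural network built from recurrent-residual
    convolution blocks and additive attention gates with cross-branch feature
    subtraction, joint training of both branches with mean-absolute-error loss,
    and evaluation of extraction quality (MSE, MAE, SNR) and fetal QRS
    detection (Pan-Tompkins peak detection scored with a timing tolerance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
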