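Package: plantstim
Title: Classification of Chemical Stimuli from Unbalanced Plant
    Electrophysiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A statistical benchmarking pipeline for classifying environmental
    chemical stimuli (NaCl, H2SO4, O3) from windowed plant electrical signals.
    Provides a synthetic signal generator with class-dependent stochastic
    structure, high-pass drift removal and non-overlapping windowing, fifteen
    higher-order statistical and nonlinear time-series features (moments,
    Hjorth parameters, detrended fluctuation analysis, rescaled-range Hurst
    exponent, wavelet-packet entropy, spectral power, Fano factor, correlation
    dimension), interquartile-range outlier filtering, principal component
    reduction with scree-threshold selection, Monte Carlo under-sampling
    evaluation of ten classifier configurations with ensemble confusion
    matrices, imbalance-aware multiclass metrics (balanced accuracy, macro F1,
    multiclass Matthews correlation coefficient), and one-way and grouped
    MANOVA trace statistics (Pillai, Wilks, Hotelling-Lawley, Roy) for
    comparing feature spaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    class,
    e1071,
    nnet,
    rpart,
    ggplot2,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
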