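Package: mfeeg
Title: Monofractal and Multifractal Features for Electrophysiological Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Epoch-wise extraction of fractal signal features from EEG and
    other uniformly sampled electrophysiological recordings. Implements the
    Higuchi fractal dimension and detrended fluctuation analysis (DFA) for
    monofractal characterization, and three multifractal singularity-spectrum
    estimators: the direct Chhabra-Jensen method and the Legendre-transform
    based MF-DFA and MF-DMA. Includes an epoch standardization and sigmoid
    mapping pipeline that decouples multifractal spectrum width from signal
    variance, simulators with known ground truth (fractional Gaussian noise
    and Brownian motion by circulant embedding, amplitude-modulated fBm, the
    binomial p-model cascade, surrogate series), conventional EEG epoch
    features (band power, line length), feature-redundancy analysis via
    Pearson correlation and Gaussian-copula mutual information, and
    experiment drivers for estimator stability and ictal/interictal effect
    size scans over sampling rate and epoch length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
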