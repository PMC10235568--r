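Package: seizecast
Title: Patient-Specific Seizure Prediction and Forecasting from Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for patient-specific seizure prediction from multichannel
    scalp EEG. Includes a synthetic long-term EEG generator with annotated
    seizures, a configurable preictal spectral signature, circadian and
    sleep-wake modulation and muscle-artifact bursts; univariate linear
    feature extraction in 5-second windows (relative spectral band powers
    and their ratios, spectral edge frequency, statistical moments, Hjorth
    parameters, decorrelation time, Daubechies-4 wavelet detail energies);
    chronological patient-specific training with preictal-period grid
    search, class balancing, stochastic-forest feature selection, weighted
    logistic regression and a voting ensemble of support vector machines;
    Firing Power smoothing of window predictions with alarm thresholding
    and refractory periods; evaluation by seizure sensitivity,
    false-positive rate per hour and time under warning, with
    surrogate-onset significance testing and a circadian forecasting
    baseline; and model-decision explanations via minimal counterfactual
    feature changes and single-feature-group retraining.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    ranger,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
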