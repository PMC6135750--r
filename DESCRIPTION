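Package: affectpipe
Title: Emotion Recognition from ECG and EEG Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for recognizing binarized
    arousal and valence from peripheral and central physiological signals.
    Extracts time-domain, frequency-domain and nonlinear heart-rate
    variability features from single-lead ECG (Pan-Tompkins beat detection,
    threshold artifact correction, smoothness-priors detrending), spectral
    band power and mean-phase-coherence connectivity features from
    9-channel EEG (rule-based epoch rejection, infomax ICA hook), reduces
    features block-wise by PCA, and classifies with sigmoid-kernel C-SVM
    under leave-one-subject-out cross-validation with SVM-RFE feature
    ranking including correlation bias reduction. Ships a synthetic
    ECG/EEG generator with known ground truth so every stage is testable
    without access to recorded human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
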