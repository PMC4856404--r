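Package: ambuhrv
Title: Short-Term Heart Rate Variability Analysis for In-Ambulance ECG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for short-term (5-minute) heart rate variability analysis of
    RR-interval series recorded under field conditions such as emergency
    ambulance transportation. Provides RR tachogram input/output and segment
    selection, ectopic-beat detection by running median filter with cubic
    spline correction, wavelet-based detrending, time-domain (SDNN, RMSSD,
    triangular index, TINN), frequency-domain (Burg autoregressive and Welch
    spectra, LF/HF ratio), nonlinear (sample entropy, detrended fluctuation
    analysis) and time-frequency (Morlet continuous wavelet scalogram LF/HF)
    metrics, a split-half reliability battery (Spearman-Brown, Cronbach's
    alpha, intraclass correlation, Bland-Altman limits of agreement), cohort
    comparison and backward-elimination logistic outcome modelling, and a
    seeded integral pulse frequency modulation (IPFM) simulator for generating
    realistic RR series and cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
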