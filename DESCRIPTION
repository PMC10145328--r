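Package: hgt
Title: Hilbert-Gauss Transform for Instantaneous Frequency and
    Respiratory Rate Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adaptive decomposition of uniformly sampled physiological
    signals into intrinsic mode functions by Gaussian average filtering
    (iterative Gaussian moving-average sifting with adaptive window
    length), Hilbert spectral analysis of the decomposed modes, and a
    mean/standard-deviation instantaneous-frequency rule that selects the
    respiratory mode and estimates respiratory rate from finger or wrist
    photoplethysmography and seismocardiography.  Includes a complex
    Morlet scalogram reference estimator for respiration-belt signals,
    intraclass correlation (two-way absolute-agreement, single measure)
    and Bland-Altman agreement statistics, and a synthetic-signal
    generator for respiration-modulated cardiac surrogates with
    controlled additive white Gaussian noise.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
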