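Package: freqtag
Title: Frequency-Tagged EEG Analysis of Infant Visual Statistical Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for steady-state (frequency-tagged) EEG studies of visual
    statistical learning in infancy. Implements the full analysis chain for
    doublet-structured shape streams tagged at a 6 Hz base rate with an
    embedded 3 Hz pair structure: stimulus protocol generation and
    transitional-probability statistics, synthetic longitudinal cohorts of
    frequency-tagged EEG blocks with 1/f noise, amplitude and
    signal-to-noise-ratio (SNR) spectra, two-criterion valid-block filtering,
    Wilcoxon-based harmonic selection, permutation maximum-statistics
    electrode thresholding and region-of-interest derivation, base/doublet
    SNR aggregation and the learning index, looking-time preference scores,
    and the longitudinal linear mixed-effects models (random intercept per
    participant) with marginal-mean contrasts, simple slopes and intraclass
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
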