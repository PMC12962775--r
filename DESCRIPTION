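Package: critEEG
Title: Criticality-Sensitive EEG Biomarkers and Their Moderation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes criticality-sensitive biomarkers from resting
    multichannel EEG: the functional excitation/inhibition ratio (fE/I) of
    narrow-band alpha oscillations with its detrended-fluctuation-analysis
    (DFA) validity gate, and the aperiodic 1/f exponent and alpha-peak
    parameters of the power spectrum. Aggregates biomarkers over ranked
    resting-state functional networks along the sensorimotor-association
    cortical hierarchy and fits covariate-adjusted linear, multilevel and
    generalized additive mixed models with hierarchy-by-IQ and
    age-by-hierarchy-by-IQ interactions, including Johnson-Neyman moderation
    probing. Ships a synthetic-data module generating alpha oscillations with
    controllable long-range temporal correlations, amplitude-fluctuation
    coupling and 1/f background, plus synthetic cohorts with known effect
    structure, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    mgcv,
    lme4,
    lmerTest,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
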