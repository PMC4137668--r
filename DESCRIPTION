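Package: ftcdlat
Title: Language Laterality Analysis for Functional Transcranial Doppler Recordings
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for functional transcranial Doppler (fTCD)
    language-laterality sessions: reading and writing two-channel cerebral
    blood-flow-velocity recordings with trial markers, marker-locked epoch
    extraction with dropout/spike screening and single-point correction,
    heart-cycle integration, normalization, extreme-value exclusion and
    baseline correction, laterality-index estimation with per-epoch
    dispersion and left/bilateral/right classification, odd/even split-half
    reliability, cohort-level statistics (chi-square family including the
    linear-by-linear trend test, t-tests, one-way ANOVA, Mann-Whitney,
    correlations, intraclass correlation, handedness quotients, language
    composite scores), a probabilistic left-brain-bias population mixture
    model, and a synthetic Doppler-session generator with known ground
    truth for end-to-end validation.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
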