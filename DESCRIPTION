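Package: CardioTMS
Title: Heart-Brain Coupling Analysis for Neuro-Cardiac-Guided TMS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for neuro-cardiac-guided transcranial magnetic
    stimulation (NCG-TMS) experiments. Builds intensity-ramped stimulation
    schedules, simulates cardiac entrainment with known ground truth (IPFM
    beat generation, synthetic ECG), detects R peaks and derives evenly
    sampled instantaneous heart rate, quantifies heart-brain coupling as
    exact-frequency spectral power at the protocol entrainment frequency
    (0.0625 Hz), and performs the downstream biostatistics: Gamma log-link
    mixed-effects models (linear and spline), FDR-corrected summaries,
    marginal contrasts versus sham, Johnson-Neyman intervals, two-way
    random-effects intraclass correlations across sessions, and post-train
    heart-rate directionality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    splines,
    mgcv,
    glmmTMB,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
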