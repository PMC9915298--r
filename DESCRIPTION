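Package: sedcut
Title: Sedentary-Time Cut-Points from Raw Thigh-Worn Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive and evaluate sedentary-time cut-points for
    thigh-worn tri-axial accelerometers from raw acceleration signals.
    Includes a synthetic-signal generator with posture ground truth
    (scripted laboratory protocols and multi-day free-living wear),
    sphere-based auto-calibration to local gravity, ENMO and MAD epoch
    metrics with non-wear detection and same-clock-time imputation,
    ROC/Youden cut-point derivation from laboratory activity means, a
    free-living daily-summary pipeline with sleep-log exclusion, and
    agreement statistics (MPE/MAPE, Bland-Altman limits of agreement,
    minimal equivalence zones) against a criterion posture-event measure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
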