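Package: bladderclock
Title: Circadian Rhythm Screening and Micturition Analytics for the Bladder Peripheral Clock
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study glucocorticoid entrainment of the bladder
    peripheral clock from the desk side: quantile normalization and
    cosine-template (MaxCorr) rhythmicity screening of clock-gene time
    courses sampled across the day, acrophase and circular phase-shift
    quantification between treatment groups, bioluminescence reporter
    trace processing (detrending, peak detection, period and
    treatment-induced phase-shift estimation), automated voided stain on
    paper (aVSOP) micturition analytics (standard-curve calibration, 8-h
    binning anchored to dark onset, volume-per-void and reference-bin
    ratios), group-by-time comparison statistics with Sidak, Bonferroni,
    Tukey and Dunnett adjustments, delta-delta-Ct relative expression,
    and synthetic-data generators with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr,
    jsonlite
Config/testthat/edition: 3
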