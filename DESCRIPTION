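Package: swaymetrics
Title: Digital Biomarkers of Postural Sway and Pronator Drift from
    Smartphone Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for smartphone-based balance testing: calibrates
    raw tri-axial 50 Hz accelerometer trials into body-axis (medio-lateral,
    antero-posterior, radial) acceleration series, derives named sway and
    pronator-drift digital biomarkers (RMS amplitude, jerkiness, spectral
    centroid and spread, stance ratios and hand asymmetries), filters them by
    ICC(2,1) test-retest reliability with Tukey-fence outlier masking, screens
    associations against clinical disability scales with Benjamini-Hochberg
    control, flags abnormal sway against a healthy-volunteer age prediction
    interval, and selects regularized (ridge/lasso/elastic-net, raw or PCA)
    disability-prediction models on an 80/20 subject split. Ships a synthetic
    cohort generator so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
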