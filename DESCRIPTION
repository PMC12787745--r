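Package: tagloc3d
Title: Three-Dimensional RSSI Localization of RFID-Tagged Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing UHF RFID-tagged animals in three dimensions
    from received signal strength (RSSI) reader logs. Implements log-distance
    path-loss calibration (reference-power and path-loss-exponent estimation),
    windowed RSSI filtering with asymmetric sigma bands, a 3D LANDMARC
    k-nearest-neighbour baseline, generative adversarial imputation (GAIN) of
    occlusion-lost readings, a dual-stream transformer locator that fuses raw
    RSSI windows with their first differences, an RF scene simulator with
    shadow fading and occlusion-driven missingness, and evaluation statistics
    (Euclidean error summaries, per-axis relative error, paired t-tests with
    effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
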