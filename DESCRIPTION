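Package: floralhum
Title: Floral Humidity Transect Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing paired-probe humidity transects across and
    above flowers: per-day probe cross-calibration, corrected focal-minus-
    background humidity differences (delta RH), measurement-quality checks
    (within-period repeatability and turbulence regression), a family of
    linear mixed models describing horizontal (quadratic) and vertical
    (logarithmic) humidity structure with AIC-based selection, peak-humidity
    summary statistics, control-threshold classification, and a
    phylogenetically controlled generalized least squares analysis of peak
    humidity against floral traits under Brownian-motion or
    Ornstein-Uhlenbeck correlation. Includes a synthetic-data generator that
    emulates the survey design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    ape,
    jsonlite
Suggests:
    nlme,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
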