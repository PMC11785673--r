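Package: phenomatch
Title: Satellite Phenometrics from EVI Time Series and Matchup with Ground Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for land-surface phenology of orchard systems from
    8-day vegetation-index composites. Computes the Enhanced Vegetation Index
    from surface reflectance, builds maximum-value composites, applies
    expert-rule quality filtering and Savitzky-Golay smoothing, fits a
    greendown-capable double-logistic model to each pixel-year, and extracts
    eight spring phenometrics (threshold, derivative, Gu tangent and Zhang
    curvature-change-rate methods). Ground phenology surveys coded on the
    BBCH scale are reduced to per-orchard phase onset dates and compared with
    the phenometrics via bias, root mean square deviation and Spearman rank
    correlation. A synthetic-data generator with known transition dates makes
    the whole pipeline testable without any satellite download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
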