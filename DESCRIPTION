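Package: lspheno
Title: Land-Surface Phenology Extraction and Hydrothermal Attribution from
    Raster Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for quantifying how vegetation phenology
    responds to hydrothermal conditions on gridded 8-day composite time
    series. Extracts start, end and length of the growing season (SOS, EOS,
    LOS) from Savitzky-Golay-smoothed EVI/MSAVI series with the dynamic
    threshold method; derives growing-season land-surface temperature,
    effective moisture and shortwave albedo layers; maps Theil-Sen slopes
    with Mann-Kendall significance stratification; attributes drivers with
    the geodetector Q statistic (factor and interaction detectors);
    computes first-order partial correlations between phenology and
    hydrothermal variables; and classifies future-trend persistence from
    rescaled-range (R/S) Hurst exponents. Ships a synthetic-data generator
    with known ground truth (double-logistic seasonal cycles, injected
    trends, stratified driver structure, fractional Gaussian noise) so the
    whole chain is testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rlang,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
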