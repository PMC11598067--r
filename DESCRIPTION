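Package: berrymetrics
Title: Metrological Validation of Image-Based Grape Berry Counting, Sizing and Volume Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the metrological validation of image-based grape
    yield estimation pipelines that count berries and measure their radii
    from single-cluster photographs. Provides validation metrics (ME, MPE,
    MAE, RMSE, error standard deviation, coefficient of variability),
    closed-form extrapolation of a single-cluster counting-error law to
    images containing many clusters via the folded-normal distribution,
    spherical-berry volume estimators with pinhole-camera pixel-to-metric
    conversion, a GUM first-order uncertainty budget with per-source
    percentage contributions and a Monte Carlo cross-check, and a synthetic
    vineyard generator (3D berry packing, rotated views with occlusion,
    detector-error emulation) so the whole chain can be exercised without
    field data. Ships the reference annotation tables of a ten-bunch
    validation study as machine-readable fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
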