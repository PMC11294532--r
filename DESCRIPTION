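Package: ftcmapr
Title: Fractional Tree Cover Mapping from Phenology-Realigned Satellite Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates fractional tree cover (percent of a pixel covered by
    trees) from annual stacks of 8-day satellite reflectance composites.
    Annual series are realigned pixel-by-pixel to a common phenology so that
    the growing-season midpoint falls at the center of the calendar year;
    twelve phase-by-band features that separate the sustained greenness
    plateau of trees from the parabolic seasonal curve of herbaceous
    vegetation are then extracted and fed to a feedforward neural-network
    regressor. Training references are built by aggregating several
    categorical forest maps to fractional cover and balancing the sample
    histogram; validation uses inclusion-probability-weighted error metrics
    for stratified reference samples. A synthetic-scene generator with
    two-endmember linear spectral mixing, phenology shifts, noise, and cloud
    gaps makes the whole pipeline testable without satellite downloads, and
    a minimal GeoTIFF reader/writer handles tile input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
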