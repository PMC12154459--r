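Package: cdrisk
Title: Dietary Cadmium Risk Assessment and Data-Driven Risk Classification
    for Processed Grain Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end risk assessment of cadmium in processed grain
    products (rice, wheat flour and other products) from laboratory
    surveillance records: parsing of non-detect and "<value" reporting
    dialects, descriptive statistics, the Nemerow integrated pollution
    index (NIPI), target cancer risk (TCR) and target hazard quotient
    (THQ) exposure indices, and a data-driven risk-level classifier built
    on a from-scratch k-means++ clusterer whose number of clusters is
    selected by rank-voting over the silhouette coefficient, Dunn index
    and Davies-Bouldin index. Includes a synthetic surveillance-data
    generator with a province-city-product hierarchy and left-censored
    log-normal concentrations for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
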