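Package: reefpressure
Title: Cumulative Human Impact and Management Indices for Less Climate-Exposed Coral Reefs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies cumulative human impact (CHI) from climate, land, and
    marine stressor categories across coral-reef bioclimatic units (BCUs) and
    the countries that contain them, for a 2013 snapshot and the 2008-2013
    change under layer-exclusion rules. Builds per-country management indices
    by directional min-max normalization of policy metrics with regional
    imputation, relates impacts to indices by regression with outlier
    sensitivity refits, and classifies units into median-split quadrants.
    Ships a seeded synthetic-world generator (rasters, polygons, metric
    tables with known ground truth) so the full pipeline is testable without
    global raster downloads, plus the packaged BCU-country membership table.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
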