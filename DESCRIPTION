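Package: dendrores
Title: Spatiotemporal Tree-Ring Resilience to Extreme Drought
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying tree resilience to extreme drought from
    ring-width measurements and monthly climate data. Reads Tucson (RWL)
    ring-width files and long-format climate tables, detrends individual
    trees with a cubic smoothing spline of specified frequency-response
    cutoff, builds biweight robust-mean site chronologies, detects extreme
    drought years from first differences of seasonal scPDSI, computes
    per-tree Lloret resistance and recovery indices around each event,
    aggregates site-level proportions of high-resistance and high-recovery
    trees, measures growth coherence (Gleichlaeufigkeit) among trees, fits
    stepwise least-squares models of climatic and stand-internal drivers,
    and maps site values onto Thiessen (Voronoi) polygons exported as
    GeoJSON. A hierarchical synthetic-data generator produces multi-site
    juniper-like datasets with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
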