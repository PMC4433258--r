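Package: fragthresh
Title: Habitat Amount, Fragmentation and Extinction Thresholds from Gridded
    Occurrence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grid-based analysis of the separate effects of forest amount and
    forest fragmentation on plant species occurrence. Computes per-cell
    percentage forest cover (PFC) and relative largest patch size (rLPS) from
    categorical land-cover rasters, fits two-predictor logistic occurrence
    models with a goodness-of-fit screen (likelihood-ratio test, AUC,
    McFadden's pseudo R-squared), derives log-ratio sensitivity scalars to
    forest contraction and to fragmentation with percentile-bootstrap
    confidence intervals, estimates an empirical maximum-fragmentation
    envelope from the PFC-rLPS point cloud, and detects extinction thresholds
    along the forest-cover gradient under contrasting fragmentation scenarios.
    Includes a synthetic-data generator (neutral landscape rasters, funnel
    shaped PFC-rLPS cell tables, virtual species) so the full pipeline can be
    exercised without land-cover downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
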