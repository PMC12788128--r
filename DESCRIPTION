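Package: nichedyn
Title: Maximum-Entropy Niche Modelling and Habitat Suitability Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for ecological niche modelling and
    habitat-dynamics analysis on aligned latitude/longitude raster grids:
    grid-cell spatial thinning of occurrence records, environmental variable
    screening by model contribution and Pearson correlation, a from-scratch
    L1-regularized maximum-entropy (MaxEnt-type) suitability model with
    feature classes and AICc tuning over a regularization-multiplier by
    feature-combination grid, Schoener's D niche overlap on kernel-density
    grids in environmental principal-component space, four-class suitability
    classification, area-based change indicators (relative change rate,
    change intensity, stability index, spatial displacement rate), centroid
    migration with Kruskal-Wallis testing, and protected-area gap analysis.
    Includes a seeded synthetic-data generator with known ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
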