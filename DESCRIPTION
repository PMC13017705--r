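Package: floracast
Title: Ensemble Species Distribution Modelling and Climate-Change Range
    Projections for Regional Floras
Version: 0.1.0
Authors@R: person("floracast", "developers", role = c("aut", "cre"),
    email = "floracast@example.org")
Description: A tested, reusable pipeline for projecting how a regional
    flora responds to future climate scenarios. Per-species habitat
    suitability is modelled with a five-learner ensemble (percentile
    envelope, Mahalanobis distance, quadratic logistic regression,
    distance-weighted k-nearest-neighbours, and boosted stumps), weighted
    by cross-validated AUC, binarized at the maximum-TSS threshold, and
    projected onto a current + 4-period x 4-scenario climate matrix.
    Downstream metrics cover area-of-habitat (AOH) change classes with a
    stability band, fold changes, extinction flags, distributional
    centroid migration vectors, stacked species richness, and per-sector
    roll-ups over a longitudinal sector mask. A virtual-species module
    generates climate grids, ground-truth ranges, and biased
    presence-only samples so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
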