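Package: omivec
Title: Discriminant-Plane Vector Analysis of Multi-Omics Colitis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the vector analysis of longitudinal multi-omics
    studies of experimental colitis. Provides a shrinkage-regularized
    multi-class Fisher discriminant ordination for small-n, large-p
    feature tables, the derived discriminant-plane statistics
    (Dissimilarity Coefficient between condition centroids, centroid
    trajectories, and the Disease Severity Index), fold-change plus
    Welch-test feature shortlisting with Benjamini-Hochberg control,
    an OTU filter / total-sum-scaling / taxonomic-aggregation pipeline
    with a Shannon-type Evenness Index, pro/anti-inflammatory ratio and
    overlap analytics, clinical disease-activity scoring, and
    condition-level correlation of inflammation markers with taxa and
    metabolic categories. A calibrated synthetic-data generator emulates
    the strain x day x treatment design of dextran-sulfate-sodium
    colitis studies so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
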