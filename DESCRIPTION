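Package: apcc
Title: Affinity Propagation Consensus Clustering for Time-Course Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised clustering of time-series gene expression profiles
    without a pre-specified number of clusters. Each profile is resampled on a
    doubled time grid with an interpolating cubic spline (not-a-knot), sliding
    windows over the grid are clustered independently by affinity propagation on
    Pearson correlation similarities, and the per-window co-cluster votes are
    averaged into a gene-relativity matrix. The relativity graph is thresholded
    over a grid, connected components give candidate partitions, small clusters
    are merged into major ones by explicit rules, and the final threshold is
    selected by the Silhouette index. External (adjusted Rand, sensitivity,
    specificity, Jaccard, Minkowski) and internal (Silhouette, Dunn,
    Davies-Bouldin) validity indices are included, together with a synthetic
    time-course generator with planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
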