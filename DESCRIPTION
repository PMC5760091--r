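Package: cytopac
Title: Partition-Assisted Clustering and Network Alignment for Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast automated gating of high-dimensional single-cell cytometry
    data by partition-assisted clustering: recursive hyper-rectangle
    partitioning of the marker space (discrepancy-guided or Bayesian
    sequential with one-step look-ahead) supplies rational initial centers,
    which are refined by a small number of k-means iterations and merged
    hierarchically under a minimum squared-Mahalanobis cluster distance.
    Subpopulations discovered per sample are linked across samples by
    multiple alignment of their marker mutual-information networks
    (maximum-relevance/minimum-redundancy edge ranking, Jaccard graph
    distance, agglomerative clade construction), which is robust to
    batch-effect mean shifts. Includes pair-counting F-measure and
    class-specific purity evaluation, elbow-point clade selection,
    constellation layouts of clade centroids, and generators for the
    Gaussian-mixture, batch-effect and dynamic benchmark scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
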