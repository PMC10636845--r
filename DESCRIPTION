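Package: tscluster
Title: Two-Step Clustering of Single-Cell RNA-Seq Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters single-cell RNA sequencing expression matrices in two
    steps: cells that sit near cluster centers ("core cells", identified by
    thresholding a weighted cell-similarity graph) are grouped by agglomerative
    hierarchical clustering under a Ward-style criterion on a random-walk graph
    distance, and the remaining boundary ("non-core") cells are then assigned
    to the nearest resulting cluster center in expression space. Includes a
    right-skewness coefficient that decides whether to log-transform the input,
    five cell-similarity metrics (Euclidean, Manhattan, Pearson, Spearman,
    shared nearest neighbours), automatic selection of the number of clusters,
    external clustering-agreement scores (ARI, NMI, AMI, accuracy), and a
    synthetic-data generator with planted clusters for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    optparse
Config/testthat/edition: 3
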