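Package: wfclust
Title: Weighted Clustering and Stability Analysis of Scientific Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of scientific (bioinformatics) workflows
    represented as directed acyclic graphs of tasks. Provides four matrix
    encodings of workflow collections (presence-absence, task occurrence,
    pair-of-tasks, pair-of-tasks with input/output ports) with per-variable
    weight vectors, weighted Euclidean and cosine distances, weighted k-means
    and k-medoids partitioning with Calinski-Harabasz, Silhouette and logSS
    cluster-validity indices for selecting the number of clusters, pairwise
    (PS) and global (PSG) clustering-stability indices computed over repeated
    randomized runs, hierarchical classification via UPGMA and
    neighbor-joining with Robinson-Foulds tree comparison and least-squares
    tree fit scoring, Rand-index evaluation against reference labels, and a
    synthetic workflow-collection generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ape,
    phangorn,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
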