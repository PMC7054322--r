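Package: subHiC
Title: Genomic Sub-Compartment Prediction from Inter-Chromosomal Hi-C
    Contacts by Graph Embedding
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts genomic sub-compartments from a normalized
    inter-chromosomal Hi-C contact map by embedding the weighted bin-bin
    interaction graph with LINE (first- and second-order proximity trained
    by negative-sampling stochastic gradient descent) and clustering the
    node vectors with k-means, with gap-statistic selection of the number
    of sub-compartments. Ships the structural evaluation used to judge an
    annotation (silhouette, a pairwise Davies-Bouldin index, and
    intra-sub-compartment network topology: weighted clustering
    coefficient, closeness and betweenness centrality), external
    validation against ChIA-PET loops (anchor assignment, loop-compartment
    matrices, intra/inter loop ratios, Fisher tests), functional
    characterization (signal and interval enrichment, intra- versus
    inter-compartment gene-expression correlation profiles), and a
    planted-partition simulator that generates every input format with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    cluster,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: HiC, Epigenetics, Clustering, GraphAndNetwork
RoxygenNote: 7.3.3
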