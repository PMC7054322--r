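# Fixture builders, generated in code at test time.

# bin table with one bin per chromosome: any edge set is valid
# (inter-chromosomal), convenient for pure graph-metric tests
toyBinTable <- function(n, resolution = 100) {
    binTableFromSeqlengths(
        stats::setNames(rep(resolution, n), paste0("chr", seq_len(n))),
        resolution)
}

toyGraph <- function(edges, n = max(edges$i, edges$j) + 1L) {
    contactGraphFromEdges(toyBinTable(n), edges$i, edges$j, edges$w)
}

# Erdos-Renyi-ish random weighted graph over n single-bin chromosomes
randomGraph <- function(n, p = 0.4, seed = 1, weighted = TRUE) {
    set.seed(seed)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) return(randomGraph(n, min(1, p * 2), seed + 1, weighted))
    ed <- data.frame(i = pairs[, 1] - 1L, j = pairs[, 2] - 1L,
                     w = if (weighted) round(runif(nrow(pairs), 0.5, 5), 3)
                         else rep(1, nrow(pairs)))
    list(edges = ed, n = n, graph = toyGraph(ed, n))
}

# isotropic Gaussian blobs with known labels
makeBlobs <- function(k, nPer, sep = 10, sd = 1, dim = 2, seed = 1) {
    set.seed(seed)
    centers <- matrix(rnorm(k * dim), k) * sep
    x <- do.call(rbind, lapply(seq_len(k), function(c)
        sweep(matrix(rnorm(nPer * dim, sd = sd), nPer), 2,
              centers[c, ], "+")))
    list(x = x, labels = rep(seq_len(k), each = nPer))
}

# small planted-partition contact graph for embedding tests
smallSim <- function(seed = 1, nChroms = 5L, binsPerChrom = 6L, K = 3L,
                     muIn = 20, muOut = 2) {
    simulateHiC(simConfig(nChroms = nChroms, binsPerChrom = binsPerChrom,
                          K = K, proportions = rep(1 / K, K),
                          muIn = muIn, muOut = muOut, seed = seed))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
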