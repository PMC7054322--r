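test_that("silhouette matches its definition on hand cases and brute force", {
    x <- matrix(c(0, 0.0001, 10, 10.0001), 4)
    lab <- c("a", "a", "b", "b")
    expect_gt(silhouetteScore(x, lab)$mean, 0.999)

    # a_i == b_i gives s_i = 0: two clusters at equal distances
    x2 <- matrix(c(0, 2, 1, 3), 4)
    lab2 <- c("a", "a", "b", "b")
    s2 <- silhouetteScore(x2, lab2)$s
    expect_equal(s2[1], 0)   # point at 0: a = 2, b = mean(1, 3) = 2

    for (seed in 1:5) {
        set.seed(seed)
        x3 <- matrix(rnorm(24), 12)
        lab3 <- sample(paste0("C", 1:3), 12, replace = TRUE)
        if (length(unique(lab3)) < 2) next
        expect_equal(silhouetteScore(x3, lab3)$s, oracleSilhouette(x3, lab3),
                     tolerance = 1e-9)
    }
    expect_error(silhouetteScore(x, rep("a", 4)), "two clusters")
})

test_that("pairwise Davies-Bouldin matches brute force and is scale-free", {
    # zero-dispersion clusters
    x <- matrix(c(1, 1, 4, 4), 4)
    expect_equal(daviesBouldinIndex(x, c("a", "a", "b", "b")), 0)

    for (seed in 1:5) {
        set.seed(seed)
        x3 <- matrix(rnorm(20), 10)
        lab3 <- sample(paste0("C", 1:3), 10, replace = TRUE)
        if (length(unique(lab3)) < 2) next
        expect_equal(daviesBouldinIndex(x3, lab3), oracleDBI(x3, lab3),
                     tolerance = 1e-9)
        expect_equal(daviesBouldinIndex(x3 * 7.3, lab3),
                     daviesBouldinIndex(x3, lab3), tolerance = 1e-9)
    }
})

test_that("compartment subgraphs equal a brute-force edge filter", {
    sim <- smallSim(seed = 3)
    g <- sim$graph
    asg <- sim$truth
    lab <- compartmentLabels(asg)
    for (l in unique(lab)) {
        sub <- compartmentSubgraph(g, asg, l)
        keep <- which(lab == l) - 1L
        ed <- graphEdges(g)
        manual <- ed[ed$i %in% keep & ed$j %in% keep, ]
        rownames(manual) <- NULL
        expect_equal(graphEdges(sub), manual)
        expect_equal(sort(attr(sub, "nodes")), sort(keep))
    }
    allOne <- subCompartmentAssignment(rep("C1", nBins(g)), sim$binTable, 1L)
    expect_equal(graphEdges(compartmentSubgraph(g, allOne, "C1")),
                 graphEdges(g))
    expect_error(compartmentSubgraph(g, asg, "C99"), "unknown label")
})

test_that("closeness matches closed forms and the shortest-path oracle", {
    path3 <- toyGraph(data.frame(i = c(0L, 1L), j = c(1L, 2L), w = 1))
    cl <- closenessCentrality(path3, "hop")
    expect_equal(unname(cl), c(2 / 3, 1, 2 / 3))

    cmpl <- toyGraph(data.frame(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L), w = 1))
    expect_equal(unname(closenessCentrality(cmpl, "hop")), rep(1, 3))

    for (seed in 1:4) {
        rg <- randomGraph(12, 0.3, seed = seed)
        for (m in c("hop", "invweight"))
            expect_equal(unname(closenessCentrality(rg$graph, m)),
                         oracleCloseness(rg$edges, 12, m),
                         tolerance = 1e-9)
    }
})

test_that("betweenness matches closed forms and exhaustive enumeration", {
    path3 <- toyGraph(data.frame(i = c(0L, 1L), j = c(1L, 2L), w = 1))
    expect_equal(unname(betweennessCentrality(path3, "hop")), c(0, 1, 0))

    cmpl <- toyGraph(data.frame(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L), w = 1))
    expect_equal(unname(betweennessCentrality(cmpl, "hop")), rep(0, 3))

    for (seed in 1:4) {
        rg <- randomGraph(10, 0.35, seed = seed + 10)
        for (m in c("hop", "invweight"))
            expect_equal(unname(betweennessCentrality(rg$graph, m)),
                         oracleBetweenness(rg$edges, 10, m),
                         tolerance = 1e-9)
    }
    # normalization divides by the pair count
    rg <- randomGraph(8, 0.5, seed = 30)
    expect_equal(unname(betweennessCentrality(rg$graph, "hop",
                                              normalized = TRUE)),
                 oracleBetweenness(rg$edges, 8, "hop") / (7 * 6 / 2),
                 tolerance = 1e-9)
})

test_that("Barrat coefficient matches hand values and the oracle", {
    tri <- toyGraph(data.frame(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L), w = 1))
    expect_equal(unname(clusteringCoefficients(tri)), rep(1, 3))

    star <- toyGraph(data.frame(i = rep(0L, 3), j = 1:3, w = 1))
    expect_equal(unname(clusteringCoefficients(star)), rep(0, 4))

    # weighted 5-node toy, hand-evaluated via the oracle
    toy <- data.frame(i = c(0L, 0L, 1L, 1L, 3L), j = c(1L, 2L, 2L, 3L, 4L),
                      w = c(1, 2, 3, 4, 5))
    expect_equal(unname(clusteringCoefficients(toyGraph(toy, 5))),
                 oracleBarrat(toy, 5), tolerance = 1e-12)

    for (seed in 1:4) {
        rg <- randomGraph(12, 0.35, seed = seed + 20)
        expect_equal(unname(clusteringCoefficients(rg$graph)),
                     oracleBarrat(rg$edges, 12), tolerance = 1e-9)
    }
})

test_that("centralities are equivariant under node relabeling", {
    rg <- randomGraph(9, 0.4, seed = 42)
    set.seed(1)
    perm <- sample(0:8)
    ed2 <- data.frame(i = pmin(perm[rg$edges$i + 1], perm[rg$edges$j + 1]),
                      j = pmax(perm[rg$edges$i + 1], perm[rg$edges$j + 1]),
                      w = rg$edges$w)
    g2 <- toyGraph(ed2, 9)
    for (f in list(closenessCentrality, betweennessCentrality)) {
        v1 <- unname(f(rg$graph))
        v2 <- unname(f(g2))
        expect_equal(v2[perm + 1], v1, tolerance = 1e-9)
    }
})

test_that("Mann-Whitney comparison reports exact and approximate p-values", {
    cm <- compareMethods(c(1, 2, 3), c(4, 5, 6))
    expect_equal(cm$p, 0.1)
    expect_equal(cm$delta, -3)

    x <- c(1.2, 3.4, 2.2, 5.0)
    same <- compareMethods(x, x)
    expect_equal(same$delta, 0)
    expect_gt(same$p, 0.9)

    # U_A + U_B = n_A * n_B
    set.seed(2)
    a <- rnorm(7); b <- rnorm(6)
    ua <- compareMethods(a, b)$U
    ub <- compareMethods(b, a)$U
    expect_equal(ua + ub, 7 * 6)
    expect_error(compareMethods(numeric(), 1:3), "empty")
})

test_that("planted labels beat shuffled labels on silhouette and DBI", {
    bl <- makeBlobs(3, 25, sep = 8, sd = 1, seed = 9)
    set.seed(9)
    shuffled <- sample(bl$labels)
    expect_gt(silhouetteScore(bl$x, bl$labels)$mean,
              silhouetteScore(bl$x, shuffled)$mean)
    expect_lt(daviesBouldinIndex(bl$x, bl$labels),
              daviesBouldinIndex(bl$x, shuffled))
})

test_that("evaluateAssignment assembles the full report", {
    sim <- smallSim(seed = 12)
    emb <- trainEmbedding(sim$graph,
        trainingConfig(dim = 8L, samples = 1e5, samplesUnit = "absolute",
                       seed = 2))
    rep <- evaluateAssignment(emb, sim$truth, sim$graph)
    expect_true(all(rep$silhouette$s >= -1 & rep$silhouette$s <= 1))
    expect_gte(rep$dbi, 0)
    expect_true(all(c("closeness", "betweenness", "clustCoef") %in%
                    names(rep$topology)))
    expect_true(all(rep$topology$closeness >= 0))
})
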