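test_that("first-order probability is the sigmoid of the dot product", {
    expect_equal(firstOrderProb(c(1, -1), c(1, 1)), 0.5)
    u <- c(1, 0, 0)
    expect_equal(firstOrderProb(u, u), 1 / (1 + exp(-1)))
    set.seed(1)
    for (r in 1:10) {
        a <- rnorm(5); b <- rnorm(5)
        expect_identical(firstOrderProb(a, b), firstOrderProb(b, a))
    }
    expect_error(firstOrderProb(1:2, 1:3), "dimensions")
})

test_that("exact first-order objective matches closed forms and edge-loop oracle", {
    g1 <- toyGraph(data.frame(i = 0L, j = 1L, w = 2))
    z <- matrix(0, 2, 4, dimnames = list(c("0", "1"), NULL))
    expect_equal(firstOrderObjective(g1, z), 2 * log(2), tolerance = 1e-12)

    rg <- randomGraph(10, 0.5, seed = 2)
    z10 <- matrix(0, 10, 3, dimnames = list(as.character(0:9), NULL))
    expect_equal(firstOrderObjective(rg$graph, z10),
                 totalWeight(rg$graph) * log(2), tolerance = 1e-12)

    set.seed(3)
    V <- matrix(rnorm(10 * 6, sd = 0.5), 10,
                dimnames = list(as.character(0:9), NULL))
    oracle <- 0
    for (r in seq_len(nrow(rg$edges)))
        oracle <- oracle - rg$edges$w[r] *
            log(1 / (1 + exp(-sum(V[rg$edges$i[r] + 1, ] *
                                  V[rg$edges$j[r] + 1, ]))))
    expect_equal(firstOrderObjective(rg$graph, V), oracle,
                 tolerance = 1e-10)
})

test_that("second-order softmax normalizes and matches direct evaluation", {
    set.seed(4)
    m <- 7
    V <- matrix(rnorm(m * 4), m, dimnames = list(as.character(0:(m - 1)), NULL))
    Cid <- matrix(rep(rnorm(4), each = m), m,
                  dimnames = list(as.character(0:(m - 1)), NULL))
    embIdent <- new("NodeEmbedding", vertex = V, context = Cid,
                    mode = "second", metadata = list())
    expect_equal(secondOrderProb(embIdent, 0, 3), 1 / m, tolerance = 1e-12)

    C <- matrix(rnorm(m * 4), m, dimnames = dimnames(V))
    emb <- new("NodeEmbedding", vertex = V, context = C, mode = "second",
               metadata = list())
    for (i in as.character(0:2)) {
        p <- secondOrderProb(emb, i, as.character(0:(m - 1)))
        expect_equal(sum(p), 1, tolerance = 1e-9)
    }
    # 3-node instance against the independent formula
    V3 <- matrix(c(1, 0, 0, 1, 0.5, -0.5), 3, byrow = TRUE,
                 dimnames = list(c("0", "1", "2"), NULL))
    C3 <- matrix(c(0.2, 0.4, -0.3, 0.1, 0.7, 0), 3, byrow = TRUE,
                 dimnames = list(c("0", "1", "2"), NULL))
    e3 <- new("NodeEmbedding", vertex = V3, context = C3, mode = "second",
              metadata = list())
    for (i in 1:3) for (j in 1:3)
        expect_equal(secondOrderProb(e3, i - 1, j - 1),
                     oracleSoftmaxProb(V3, C3, i, j), tolerance = 1e-12)
})

test_that("exact second-order objective matches closed form and brute force", {
    rg <- randomGraph(8, 0.5, seed = 5)
    m <- 8
    z <- new("NodeEmbedding",
             vertex = matrix(0, m, 3, dimnames = list(as.character(0:7), NULL)),
             context = matrix(0, m, 3, dimnames = list(as.character(0:7), NULL)),
             mode = "second", metadata = list())
    expect_equal(secondOrderObjective(rg$graph, z),
                 2 * totalWeight(rg$graph) * log(m), tolerance = 1e-10)

    set.seed(6)
    V <- matrix(rnorm(m * 5, sd = 0.6), m, dimnames = list(as.character(0:7), NULL))
    C <- matrix(rnorm(m * 5, sd = 0.6), m, dimnames = list(as.character(0:7), NULL))
    emb <- new("NodeEmbedding", vertex = V, context = C, mode = "second",
               metadata = list())
    oracle <- 0
    for (r in seq_len(nrow(rg$edges))) {
        i <- rg$edges$i[r] + 1; j <- rg$edges$j[r] + 1; w <- rg$edges$w[r]
        oracle <- oracle - w * (log(oracleSoftmaxProb(V, C, i, j)) +
                                log(oracleSoftmaxProb(V, C, j, i)))
    }
    expect_equal(secondOrderObjective(rg$graph, emb), oracle,
                 tolerance = 1e-10)
})

test_that("alias sampler reproduces edge and noise distributions", {
    g <- toyGraph(data.frame(i = c(0L, 2L), j = c(1L, 3L), w = c(1, 3)))
    smp <- buildSampler(g, seed = 11)
    expect_equal(sum(smp$edgeProb), 1, tolerance = 1e-12)
    expect_equal(sum(smp$nodeProb), 1, tolerance = 1e-12)
    draws <- sampleEdges(smp, 1e5)
    f1 <- mean(draws == 1)
    expect_lt(abs(f1 - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))

    g1 <- toyGraph(data.frame(i = 0L, j = 1L, w = 2))
    expect_true(all(sampleEdges(buildSampler(g1, 1), 1000) == 1))

    # equal weights: uniform draw frequencies (chi-square)
    ge <- toyGraph(data.frame(i = c(0L, 0L, 2L, 4L), j = c(1L, 3L, 5L, 5L),
                              w = rep(2, 4)))
    dr <- sampleEdges(buildSampler(ge, 7), 4e4)
    cs <- chisq.test(table(factor(dr, levels = 1:4)))
    expect_gt(cs$p.value, 0.01)

    # noise draws follow degree^0.75
    sim <- smallSim(seed = 8)
    smp2 <- buildSampler(sim$graph, seed = 3)
    nd <- sampleNegatives(smp2, 2e5)
    emp <- tabulate(nd + 1L, nbins = nBins(sim$graph)) / 2e5
    expect_lt(max(abs(emp - smp2$nodeProb)), 0.01)
})

test_that("negative-sampling updates match central finite differences", {
    set.seed(10)
    relErr <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-4))
    h <- 1e-5
    for (r in 1:30) {
        d <- sample(3:8, 1)
        ui <- rnorm(d); uj <- rnorm(d)
        lab <- sample(c("pos", "neg"), 1)
        loss1 <- function(v) {
            a <- v[1:d]; b <- v[-(1:d)]
            s <- sum(a * b)
            if (lab == "pos") -log(1 / (1 + exp(-s)))
            else -log(1 / (1 + exp(s)))
        }
        up <- sgdUpdateFirst(ui, uj, lab, lr = 1)
        grad <- c(ui - up$ui, uj - up$uj)   # lr = 1: grad = old - new
        v0 <- c(ui, uj)
        fd <- vapply(seq_along(v0), function(q) {
            e <- numeric(length(v0)); e[q] <- h
            (loss1(v0 + e) - loss1(v0 - e)) / (2 * h)
        }, numeric(1))
        expect_lt(relErr(grad, fd), 1e-5)

        # second order: positive context + 2 negatives
        ctxP <- rnorm(d); ctxN <- matrix(rnorm(2 * d), 2)
        loss2 <- function(v) {
            a <- v[1:d]; p <- v[(d + 1):(2 * d)]
            n <- matrix(v[-(1:(2 * d))], 2)
            -log(1 / (1 + exp(-sum(p * a)))) -
                sum(log(1 / (1 + exp(drop(n %*% a)))))
        }
        up2 <- sgdUpdateSecond(ui, ctxP, ctxN, lr = 1)
        grad2 <- c(ui - up2$ui, ctxP - up2$ctxPos,
                   as.numeric(ctxN - up2$ctxNeg))
        v0 <- c(ui, ctxP, as.numeric(ctxN))
        fd2 <- vapply(seq_along(v0), function(q) {
            e <- numeric(length(v0)); e[q] <- h
            (loss2(v0 + e) - loss2(v0 - e)) / (2 * h)
        }, numeric(1))
        expect_lt(relErr(grad2, fd2), 1e-5)
    }
})

test_that("update magnitude scales with lr and saturates appropriately", {
    ui <- c(10, 10); uj <- c(10, 10)     # saturated positive pair
    up <- sgdUpdateFirst(ui, uj, "pos", lr = 0.1)
    expect_lt(max(abs(up$ui - ui)), 1e-10)

    set.seed(12)
    a <- rnorm(4); b <- rnorm(4)
    u1 <- sgdUpdateFirst(a, b, "pos", lr = 0.01)
    u2 <- sgdUpdateFirst(a, b, "pos", lr = 0.02)
    expect_equal(u2$ui - a, 2 * (u1$ui - a), tolerance = 1e-9)

    # with no negatives the positive context alignment increases
    ui <- rnorm(4); ctx <- ui
    up2 <- sgdUpdateSecond(ui, ctx, NULL, lr = 0.5)
    expect_gt(sum(up2$ctxPos * up2$ui), sum(ctx * ui))
})

test_that("training decreases the exact objectives on a small fixture", {
    sim <- smallSim(seed = 2)
    g <- sim$graph
    cfg <- trainingConfig(dim = 16L, samples = 5e4,
                          samplesUnit = "absolute", seed = 4)
    emb <- trainEmbedding(g, cfg)
    e0 <- initialEmbedding(emb)
    expect_lt(firstOrderObjective(g, emb), firstOrderObjective(g, e0))
    expect_lt(secondOrderObjective(g, emb), secondOrderObjective(g, e0))
})

test_that("joint mixing, determinism and separate-mode shape behave as specified", {
    sim <- smallSim(seed = 2)
    g <- sim$graph
    cfg <- trainingConfig(dim = 8L, samples = 2e4, samplesUnit = "absolute",
                          alpha = 1, seed = 1)
    emb <- trainEmbedding(g, cfg)
    expect_equal(emb@metadata$nFirst, 0)
    expect_equal(emb@metadata$nSecond, 2e4)

    cfg2 <- trainingConfig(dim = 8L, samples = 2e4,
                           samplesUnit = "absolute", seed = 9)
    expect_identical(vertexVectors(trainEmbedding(g, cfg2)),
                     vertexVectors(trainEmbedding(g, cfg2)))

    cfgSep <- trainingConfig(dim = 8L, samples = 3e4,
                             samplesUnit = "absolute", mode = "separate",
                             seed = 1)
    es <- trainEmbedding(g, cfgSep)
    V <- vertexVectors(es)
    expect_equal(ncol(V), 16L)
    # each half row-normalized
    expect_equal(unname(rowSums(V[, 1:8]^2)), rep(1, nrow(V)),
                 tolerance = 1e-9)
    expect_equal(unname(rowSums(V[, 9:16]^2)), rep(1, nrow(V)),
                 tolerance = 1e-9)
})

test_that("embeddings separate planted blocks in cosine similarity", {
    sim <- smallSim(seed = 7)
    emb <- trainEmbedding(sim$graph,
        trainingConfig(dim = 16L, samples = 2e5, samplesUnit = "absolute",
                       seed = 5))
    V <- vertexVectors(emb)
    Vn <- V / sqrt(rowSums(V^2))
    lab <- compartmentLabels(sim$truth)[as.integer(rownames(V)) + 1L]
    S <- Vn %*% t(Vn)
    same <- outer(lab, lab, "==")
    diag(S) <- NA
    expect_gt(mean(S[same], na.rm = TRUE), mean(S[!same], na.rm = TRUE))
})

test_that("degenerate training inputs are rejected", {
    bt <- toyBinTable(3)
    g <- contactGraphFromEdges(bt, 0L, 1L, 1)
    expect_error(trainingConfig(alpha = 1.5), "alpha")
    expect_error(trainingConfig(negative = 0), "negative")
    g0 <- contactGraphFromEdges(bt, integer(), integer(), numeric())
    expect_error(trainEmbedding(g0), "at least 2 connected")
    expect_error(buildSampler(g0), "empty graph")
})
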