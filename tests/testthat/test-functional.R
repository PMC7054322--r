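test_that("bin signal aggregation is a coverage-weighted mean", {
    bt <- binTableFromSeqlengths(c(chr1 = 300), 100)
    # constant track
    tr <- data.frame(chrom = "chr1", start = 0, end = 300, value = 2.5)
    bs <- aggregateSignal(tr, bt)
    expect_equal(bs$signal, rep(2.5, 3))
    expect_equal(bs$coverage, rep(1, 3))

    # two half-bin intervals, values 2 and 4 -> bin mean 3
    tr2 <- data.frame(chrom = "chr1", start = c(0, 50), end = c(50, 100),
                      value = c(2, 4))
    expect_equal(aggregateSignal(tr2, bt)$signal[1], 3)

    expect_error(aggregateSignal(
        data.frame(chrom = "chr1", start = 250, end = 350, value = 1), bt),
        "beyond chromosome end")
})

test_that("aggregation agrees with a base-pair oracle and conserves mass", {
    bt <- binTableFromSeqlengths(c(chr1 = 500, chr2 = 300), 100)
    set.seed(3)
    # random non-overlapping toy track
    mk <- function(chrom, len) {
        cuts <- sort(sample(0:len, 8))
        starts <- cuts[seq(1, 7, by = 2)]
        ends <- cuts[seq(2, 8, by = 2)]
        ok <- ends > starts
        data.frame(chrom = chrom, start = starts[ok], end = ends[ok],
                   value = round(runif(sum(ok), 0, 5), 2))
    }
    tr <- rbind(mk("chr1", 500), mk("chr2", 300))
    bs <- aggregateSignal(tr, bt)

    # base-pair level accumulation
    bpVal <- list(chr1 = rep(NA_real_, 500), chr2 = rep(NA_real_, 300))
    for (r in seq_len(nrow(tr)))
        bpVal[[tr$chrom[r]]][(tr$start[r] + 1):tr$end[r]] <- tr$value[r]
    gr <- bins(bt)
    for (r in seq_len(nrow(bs))) {
        b <- bs$node_id[r] + 1L
        v <- bpVal[[as.character(GenomicRanges::seqnames(gr)[b])]][
            GenomicRanges::start(gr)[b]:GenomicRanges::end(gr)[b]]
        expect_equal(bs$signal[r], mean(v, na.rm = TRUE), tolerance = 1e-9)
    }
    # mass conservation over covered regions
    lhs <- sum(bs$signal * bs$coverage * GenomicRanges::width(gr)[bs$node_id + 1])
    rhs <- sum(tr$value * (tr$end - tr$start))
    expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("median enrichment behaves on hand-built label structures", {
    bt <- toyBinTable(8)
    asg <- subCompartmentAssignment(
        c("C1", "C1", "C2", "C2", "C2", "C2", "C2", "C2"), bt, k = 2L)
    # constant signal -> enrichment 1 everywhere
    bs <- data.frame(node_id = 0:7, signal = rep(3, 8), coverage = 1)
    expect_equal(unname(signalEnrichment(bs, asg)), c(1, 1))

    # minority compartment at 2v, rest at v: overall median v
    bs2 <- data.frame(node_id = 0:7, signal = c(2, 2, 1, 1, 1, 1, 1, 1),
                      coverage = 1)
    en <- signalEnrichment(bs2, asg)
    expect_equal(unname(en["C1"]), 2)
    expect_equal(unname(en["C2"]), 1)

    # scale invariance
    bs3 <- bs2; bs3$signal <- bs3$signal * 13.7
    expect_equal(signalEnrichment(bs3, asg), en, tolerance = 1e-12)

    # label with no covered bins is NA, not 0
    bs4 <- data.frame(node_id = 2:7, signal = rep(2, 6), coverage = 1)
    expect_true(is.na(signalEnrichment(bs4, asg)["C1"]))

    bs0 <- data.frame(node_id = 0:7, signal = rep(0, 8), coverage = 1)
    expect_error(signalEnrichment(bs0, asg), "median")
})

test_that("interval enrichment uses the midpoint rule", {
    bt <- toyBinTable(10)   # 10 chroms x 100 bp
    asg <- subCompartmentAssignment(
        c(rep("C1", 2), rep("C2", 8)), bt, k = 2L)
    gr <- bins(bt)
    # all intervals inside C1 bins
    iv <- data.frame(chrom = c("chr1", "chr2"), start = c(10, 20),
                     end = c(30, 60))
    en <- intervalEnrichment(iv, asg)
    expect_equal(unname(en["C1"]), 10 / 2)   # total_bins / #C1_bins
    expect_equal(unname(en["C2"]), 0)

    # uniform intervals: one per bin, dead-center
    ivu <- data.frame(chrom = paste0("chr", 1:10), start = 40, end = 60)
    enu <- intervalEnrichment(ivu, asg)
    expect_equal(unname(enu), c(1, 1), tolerance = 1e-12)

    expect_error(intervalEnrichment(iv[0, ], asg), "empty")
})

test_that("identical expression vectors give Spearman rho 1 pairs", {
    bt <- toyBinTable(4, resolution = 1000)
    # put two genes on one chromosome in the same bin
    asg <- subCompartmentAssignment(c("C1", "C1", "C2", "C2"), bt, k = 2L)
    expr <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       tss = c(100, 200),
                       expr_rep1 = c(1, 2), expr_rep2 = c(2, 4),
                       expr_rep3 = c(3, 6), expr_rep4 = c(5, 10))
    pr <- expressionCorrelationProfile(expr, asg, maxDist = 1000,
                                       step = 1000, sigFilter = FALSE)
    expect_equal(pr$meanIntra, 1)
    expect_equal(pr$nIntra, 1L)
})

test_that("correlation profile is symmetric under replicate reordering", {
    sim <- simulateHiC(simConfig(nChroms = 3, binsPerChrom = 20, K = 3,
                                 proportions = rep(1 / 3, 3), seed = 21))
    ex <- simulateExpression(sim$truth, nGenes = 80, nReps = 5,
                             sharedFactorSd = 1.5, seed = 2)
    repCols <- grep("^expr_rep", names(ex))
    ex2 <- ex
    ex2[, repCols] <- ex[, rev(repCols)]
    names(ex2)[repCols] <- names(ex)[repCols]
    p1 <- expressionCorrelationProfile(ex, sim$truth, maxDist = 1e6,
                                       step = 5e5, sigFilter = FALSE)
    p2 <- expressionCorrelationProfile(ex2, sim$truth, maxDist = 1e6,
                                       step = 5e5, sigFilter = FALSE)
    expect_equal(p1$meanIntra, p2$meanIntra, tolerance = 1e-12)
    expect_equal(p1$meanInter, p2$meanInter, tolerance = 1e-12)
})
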