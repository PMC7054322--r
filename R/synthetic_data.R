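## Planted-partition generators: Hi-C-like inter-chromosomal contacts with
## block structure, loops biased toward intra-compartment anchors, and
## compartment-correlated signal and expression tables. Every generator is
## a pure function of (config, seed) so each pipeline stage can be scored
## against known truth.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package's own validation
#' runs under: 6 chromosomes x 40 bins at 100 kb, K = 5 equally likely
#' planted sub-compartments, Poisson contact weights with mean 20 within a
#' compartment and 2 between, 2000 loops of which 80\% join two bins of
#' the same compartment, and compartment-graded signal effects.
#'
#' @param nChroms number of chromosomes.
#' @param binsPerChrom bins per chromosome.
#' @param resolution bin width in bp.
#' @param K number of planted sub-compartments.
#' @param proportions label mixing proportions (sum to 1).
#' @param muIn,muOut mean Poisson contact weight for same-/different-label
#'   inter-chromosomal bin pairs (\code{muIn > muOut >= 0}).
#' @param dispersion NA for Poisson weights (default); a finite positive
#'   value draws negative-binomial weights with that \code{size}
#'   parameter, for overdispersed counts.
#' @param nLoops number of simulated ChIA-PET loops.
#' @param pIntra probability a loop joins two bins of one compartment.
#' @param anchorWidth loop anchor width in bp (at most the resolution).
#' @param petGeomP success probability of the shifted-geometric PET count
#'   (mean 1 + (1-p)/p).
#' @param signalEffects per-label mean signal (length K, decreasing by
#'   convention so C1 is "open").
#' @param signalNoiseSd Gaussian noise sd on the signal.
#' @param seed integer seed.
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(nChroms = 6L, binsPerChrom = 40L, resolution = 1e5,
                      K = 5L, proportions = rep(1 / K, K),
                      muIn = 20, muOut = 2, dispersion = NA,
                      nLoops = 2000L, pIntra = 0.8, anchorWidth = 1e4,
                      petGeomP = 0.1,
                      signalEffects = seq(2 * K, 2, by = -2),
                      signalNoiseSd = 1, seed = 1L) {
    if (K > nChroms * binsPerChrom) stop("K exceeds the number of bins")
    if (abs(sum(proportions) - 1) > 1e-8)
        stop("proportions must sum to 1")
    if (!(muIn > muOut)) stop("muIn must exceed muOut")
    if (muOut < 0) stop("muOut must be >= 0")
    if (pIntra < 0 || pIntra > 1) stop("pIntra must lie in [0, 1]")
    if (anchorWidth > resolution) stop("anchorWidth exceeds the resolution")
    if (length(signalEffects) != K) stop("one signal effect per label")
    structure(list(nChroms = as.integer(nChroms),
                   binsPerChrom = as.integer(binsPerChrom),
                   resolution = resolution, K = as.integer(K),
                   proportions = proportions, muIn = muIn, muOut = muOut,
                   dispersion = dispersion, nLoops = as.integer(nLoops),
                   pIntra = pIntra, anchorWidth = anchorWidth,
                   petGeomP = petGeomP, signalEffects = signalEffects,
                   signalNoiseSd = signalNoiseSd, seed = as.integer(seed)),
              class = "SimConfig")
}

#' Simulate planted-partition inter-chromosomal Hi-C contacts
#'
#' Every bin draws a latent sub-compartment label independently (so each
#' compartment spans all chromosomes, as real sub-compartments do). Every
#' inter-chromosomal bin pair then draws a contact weight from
#' Poisson(muIn) when the labels match and Poisson(muOut) otherwise
#' (negative binomial when \code{dispersion} is set); zero weights are
#' omitted.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{binTable}, \code{graph} (a
#'   \code{ContactGraph}), and \code{truth} (the planted labels as a
#'   \code{SubCompartmentAssignment}).
#' @export
simulateHiC <- function(config = simConfig()) {
    set.seed(config$seed)
    sl <- stats::setNames(rep(config$binsPerChrom * config$resolution,
                              config$nChroms),
                          paste0("chr", seq_len(config$nChroms)))
    bt <- binTableFromSeqlengths(sl, config$resolution)
    n <- nBins(bt)
    z <- sample.int(config$K, n, replace = TRUE, prob = config$proportions)
    chrom <- as.character(seqnames(bins(bt)))
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pr[, 1] - 1L; j <- pr[, 2] - 1L
    inter <- chrom[i + 1L] != chrom[j + 1L]
    i <- i[inter]; j <- j[inter]
    mu <- ifelse(z[i + 1L] == z[j + 1L], config$muIn, config$muOut)
    w <- if (is.finite(config$dispersion))
        stats::rnbinom(length(mu), size = config$dispersion, mu = mu)
    else stats::rpois(length(mu), mu)
    keep <- w > 0
    graph <- contactGraphFromEdges(bt, i[keep], j[keep], w[keep])
    truth <- subCompartmentAssignment(paste0("C", z), bt, k = config$K)
    list(binTable = bt, graph = graph, truth = truth)
}

# bins (0-based ids) of each label on each chromosome
labelChromIndex <- function(truth) {
    gr <- bins(truth)
    data.frame(id = mcols(gr)$node_id,
               chrom = as.character(seqnames(gr)),
               lab = compartmentLabels(truth))
}

#' Simulate ChIA-PET loops over planted labels
#'
#' Each loop picks a chromosome; with probability \code{pIntra} both
#' anchors come from bins of one label on that chromosome, otherwise from
#' bins of two different labels. Anchors of \code{anchorWidth} bp are
#' centered in their bins, left anchor upstream of the right one, and PET
#' counts follow a shifted geometric distribution (>= 1). All loops are
#' intra-chromosomal by construction.
#'
#' @param truth a \code{SubCompartmentAssignment} of planted labels.
#' @param config a \code{\link{simConfig}}.
#' @return a \code{LoopSet}.
#' @export
simulateLoops <- function(truth, config = simConfig()) {
    set.seed(config$seed + 1L)
    idx <- labelChromIndex(truth)
    idx <- idx[!is.na(idx$lab), , drop = FALSE]
    byChrom <- split(idx, idx$chrom)
    # chromosomes where an intra pair (one label, 2+ bins) exists
    canIntra <- vapply(byChrom, function(d) any(table(d$lab) >= 2),
                       logical(1))
    canInter <- vapply(byChrom, function(d) length(unique(d$lab)) >= 2,
                       logical(1))
    if (!any(canIntra) && config$pIntra > 0)
        stop("no chromosome offers a same-label bin pair")
    if (!any(canInter) && config$pIntra < 1)
        stop("no chromosome offers a different-label bin pair")
    gr <- bins(truth)
    res <- config$resolution
    half <- config$anchorWidth / 2
    rows <- vector("list", config$nLoops)
    for (l in seq_len(config$nLoops)) {
        intra <- stats::runif(1) < config$pIntra
        pool <- byChrom[if (intra) canIntra else canInter]
        d <- pool[[sample.int(length(pool), 1L)]]
        if (intra) {
            labs <- names(which(table(d$lab) >= 2))
            lab <- labs[sample.int(length(labs), 1L)]
            ids <- sample(d$id[d$lab == lab], 2L)
        } else {
            labs <- sample(unique(d$lab), 2L)
            ids <- c(sample(d$id[d$lab == labs[1]], 1L),
                     sample(d$id[d$lab == labs[2]], 1L))
        }
        ids <- sort(ids)
        ctr <- (start(gr)[ids + 1L] - 1L) + width(gr)[ids + 1L] / 2
        rows[[l]] <- data.frame(
            chrom1 = d$chrom[1L], start1 = ctr[1] - half, end1 = ctr[1] + half,
            chrom2 = d$chrom[1L], start2 = ctr[2] - half, end2 = ctr[2] + half,
            name = sprintf("loop%d", l),
            pet = 1L + stats::rgeom(1L, config$petGeomP))
    }
    loopSet(do.call(rbind, rows), minPet = 1L, petColumn = "pet")
}

#' Simulate a compartment-graded signal track
#'
#' Per-bin value = effect of the bin's planted label + Gaussian noise,
#' clipped at 0; one bedGraph interval per bin.
#'
#' @param truth planted labels (\code{SubCompartmentAssignment}).
#' @param effects per-label mean signal, one value per label C1..Ck.
#' @param noiseSd Gaussian noise sd (>= 0).
#' @param seed integer seed.
#' @return bedGraph data.frame (\code{chrom, start, end, value}).
#' @export
simulateSignal <- function(truth, effects, noiseSd = 1, seed = 1L) {
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    lab <- compartmentLabels(truth)
    k <- nCompartments(truth)
    if (length(effects) != k) stop("one effect per label required")
    set.seed(seed)
    mu <- effects[as.integer(sub("^C", "", lab))]
    val <- pmax(0, mu + stats::rnorm(length(mu), sd = noiseSd))
    gr <- bins(truth)
    data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
               end = end(gr), value = val)
}

#' Simulate an expression table with compartment-shared factors
#'
#' Genes are placed uniformly over bins (TSS at the bin center). Each
#' replicate draws one latent co-expression factor per compartment and
#' chromosome (sd = \code{sharedFactorSd}; compartment-level co-regulation
#' acts within its chromosomal neighborhood) plus one global batch factor
#' shared by all genes (sd = \code{batchSd}, mimicking depth/batch
#' variation between RNA-seq replicates); a gene's expression in that
#' replicate is batch factor + compartment factor + gene baseline +
#' Gaussian noise, clipped to be nonnegative. Same-chromosome genes of the
#' same compartment therefore co-vary more strongly across replicates than
#' genes of different compartments; with \code{sharedFactorSd = 0} the two
#' groups co-vary identically (the null for the intra/inter correlation
#' ratio).
#'
#' @param truth planted labels.
#' @param nGenes number of genes.
#' @param nReps number of replicates (>= 3).
#' @param sharedFactorSd sd of the per-replicate compartment factor; 0
#'   removes the compartment structure (null model).
#' @param noiseSd per-gene, per-replicate noise sd.
#' @param batchSd sd of the per-replicate global factor.
#' @param seed integer seed.
#' @return data.frame: \code{gene_id, chrom, tss, expr_rep1..N}.
#' @export
simulateExpression <- function(truth, nGenes = 300L, nReps = 6L,
                               sharedFactorSd = 1, noiseSd = 1,
                               batchSd = 2, seed = 1L) {
    if (nReps < 3L) stop("need at least 3 replicates")
    set.seed(seed)
    gr <- bins(truth)
    lab <- compartmentLabels(truth)
    ok <- which(!is.na(lab))
    binIdx <- sample(ok, nGenes, replace = TRUE)
    z <- as.integer(sub("^C", "", lab[binIdx]))
    chrom <- as.character(seqnames(gr))
    chromLv <- unique(chrom)
    h <- match(chrom[binIdx], chromLv)
    K <- nCompartments(truth)
    # factor per (compartment, chromosome, replicate)
    factorArr <- array(stats::rnorm(K * length(chromLv) * nReps,
                                    sd = sharedFactorSd),
                       c(K, length(chromLv), nReps))
    factorMat <- matrix(factorArr[cbind(rep(z, nReps),
                                        rep(h, nReps),
                                        rep(seq_len(nReps), each = nGenes))],
                        nGenes, nReps)
    batch <- stats::rnorm(nReps, sd = batchSd)
    baseline <- stats::rnorm(nGenes, mean = 5, sd = 1)
    E <- factorMat + baseline +
        matrix(batch, nGenes, nReps, byrow = TRUE) +
        matrix(stats::rnorm(nGenes * nReps, sd = noiseSd), nGenes, nReps)
    E <- pmax(E, 0)
    out <- data.frame(gene_id = sprintf("gene%d", seq_len(nGenes)),
                      chrom = as.character(seqnames(gr))[binIdx],
                      tss = (start(gr)[binIdx] - 1L) +
                          floor(width(gr)[binIdx] / 2))
    colnames(E) <- sprintf("expr_rep%d", seq_len(nReps))
    cbind(out, as.data.frame(E))
}

#' Write an expression table as TSV
#'
#' @param expr data.frame from \code{\link{simulateExpression}}.
#' @param path output path.
#' @export
writeExpressionTable <- function(expr, path) {
    utils::write.table(expr, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
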