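## Functional characterization of a sub-compartment annotation: per-bin
## signal aggregation and enrichment, interval-annotation enrichment, and
## intra- vs inter-compartment gene-expression correlation profiles.

#' Read a bedGraph track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @return data.frame with columns \code{chrom, start, end, value}.
#' @export
readBedGraph <- function(path) {
    utils::read.table(path, sep = "\t", header = FALSE,
                      comment.char = "#", stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric"))
}

#' Write a bedGraph track
#'
#' @param track data.frame with columns \code{chrom, start, end, value}.
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
    utils::write.table(
        data.frame(track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   track$value),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' Coverage-weighted mean signal per bin
#'
#' Aggregates a bedGraph track to the bin grid: each bin's value is the
#' mean of the track over the covered base pairs, weighting every interval
#' by its overlap width. Bins the track never touches are absent from the
#' result.
#'
#' @param track a bedGraph data.frame (\code{chrom, start, end, value}) or
#'   a file path.
#' @param binTable a \code{BinTable}.
#' @return data.frame with columns \code{node_id}, \code{signal}, and
#'   \code{coverage} (fraction of the bin covered by the track).
#' @export
aggregateSignal <- function(track, binTable) {
    if (is.character(track)) track <- readBedGraph(track)
    if (any(!is.finite(track$value))) stop("non-finite track value")
    gr <- bins(binTable)
    q <- GRanges(track$chrom, IRanges(start = track$start + 1,
                                      end = track$end))
    chromEnd <- tapply(end(gr), as.character(seqnames(gr)), max)
    if (any(track$end > chromEnd[track$chrom]))
        stop("track interval beyond chromosome end")
    hits <- suppressWarnings(findOverlaps(q, gr))
    if (!length(hits))
        return(data.frame(node_id = integer(), signal = numeric(),
                          coverage = numeric()))
    bp <- width(pintersect(q[queryHits(hits)], gr[subjectHits(hits)]))
    id <- mcols(gr)$node_id[subjectHits(hits)]
    val <- track$value[queryHits(hits)]
    mass <- rowsum(val * bp, id)
    cov <- rowsum(bp, id)
    ids <- as.integer(rownames(mass))
    ord <- order(ids)
    data.frame(node_id = ids[ord],
               signal = (mass[, 1] / cov[, 1])[ord],
               coverage = (cov[, 1] / width(gr)[match(ids, mcols(gr)$node_id)])[ord],
               row.names = NULL)
}

#' Median signal enrichment per sub-compartment
#'
#' Enrichment of a sub-compartment is the median signal over its covered
#' bins divided by the median over all covered bins genome-wide. Bins
#' without signal are excluded from both medians; a sub-compartment with
#' no covered bins is reported NA.
#'
#' @param binSignal output of \code{\link{aggregateSignal}}.
#' @param assignment a \code{SubCompartmentAssignment}.
#' @return named numeric vector of enrichments, one per label C1..Ck.
#' @export
signalEnrichment <- function(binSignal, assignment) {
    lab <- compartmentLabels(assignment)
    sig <- binSignal$signal
    sigLab <- lab[binSignal$node_id + 1L]
    overall <- stats::median(sig)
    if (!is.finite(overall) || overall == 0)
        stop("genome-wide median signal is zero or undefined")
    lv <- paste0("C", seq_len(nCompartments(assignment)))
    vapply(lv, function(l) {
        v <- sig[!is.na(sigLab) & sigLab == l]
        if (!length(v)) NA_real_ else stats::median(v) / overall
    }, numeric(1))
}

#' Interval-annotation enrichment per sub-compartment
#'
#' For an annotation such as enhancers or super-enhancers, the enrichment
#' of a sub-compartment is the observed rate of intervals per bin of that
#' sub-compartment over the genome-wide rate. Intervals are attributed to
#' the bin containing their midpoint by default (\code{rule = "any"}
#' counts an interval once for every label whose bins it touches).
#'
#' @param intervals data.frame with columns \code{chrom, start, end}
#'   (0-based half-open) or a BED file path.
#' @param assignment a \code{SubCompartmentAssignment}.
#' @param rule \code{"midpoint"} (default) or \code{"any"}.
#' @return named numeric vector of enrichments per label (0 for a label
#'   receiving no intervals; NA for a label with no bins).
#' @export
intervalEnrichment <- function(intervals, assignment,
                               rule = c("midpoint", "any")) {
    rule <- match.arg(rule)
    if (is.character(intervals)) {
        intervals <- utils::read.table(intervals, sep = "\t", header = FALSE,
                                       comment.char = "#",
                                       stringsAsFactors = FALSE)[, 1:3]
        names(intervals) <- c("chrom", "start", "end")
    }
    if (!nrow(intervals)) stop("empty interval set")
    lab <- compartmentLabels(assignment)
    gr <- bins(assignment)
    lv <- paste0("C", seq_len(nCompartments(assignment)))
    if (rule == "midpoint") {
        mid <- floor((intervals$start + intervals$end) / 2)
        q <- GRanges(intervals$chrom, IRanges(start = mid + 1, width = 1))
    } else {
        q <- GRanges(intervals$chrom,
                     IRanges(start = intervals$start + 1,
                             end = intervals$end))
    }
    hits <- suppressWarnings(findOverlaps(q, gr))
    hitLab <- lab[subjectHits(hits)]
    if (rule == "any") {
        seen <- !duplicated(data.frame(queryHits(hits), hitLab))
        hitLab <- hitLab[seen]
    }
    counts <- table(factor(hitLab, levels = lv))
    binsPer <- table(factor(lab, levels = lv))
    nAssigned <- sum(!is.na(lab))
    overallRate <- sum(counts) / nAssigned
    out <- vapply(lv, function(l) {
        if (binsPer[[l]] == 0L) return(NA_real_)
        (counts[[l]] / binsPer[[l]]) / overallRate
    }, numeric(1))
    out
}

#' Intra- vs inter-compartment gene-expression correlation profile
#'
#' For each distance ceiling D in \code{seq(step, maxDist, step)}, all
#' same-chromosome TSS pairs at most D apart are formed; a pair is
#' intra-compartment when both TSSs fall in bins with the same label. The
#' Spearman correlation of the two genes' expression across replicates is
#' computed per pair, and the mean correlation over significant pairs
#' (p < 0.05; optional) is reported for the intra and inter groups, along
#' with their ratio. Genes must be expressed (> 0) in at least one
#' replicate.
#'
#' @param expr data.frame: \code{gene_id, chrom, tss} then one numeric
#'   column per replicate (at least 3 when \code{sigFilter} is on).
#' @param assignment a \code{SubCompartmentAssignment}.
#' @param maxDist largest pair distance in bp (default 10 Mb).
#' @param step distance step in bp (default 100 kb).
#' @param sigFilter keep only pairs with Spearman p < 0.05 in the filtered
#'   means (the unfiltered means are always reported too).
#' @return data.frame with one row per distance ceiling: \code{dist},
#'   pair counts, filtered means \code{meanIntra}/\code{meanInter} and
#'   \code{ratio}, plus unfiltered \code{meanIntraAll}/\code{meanInterAll}
#'   and \code{ratioAll}. Distance bins without qualifying pairs carry NA.
#' @export
expressionCorrelationProfile <- function(expr, assignment, maxDist = 1e7,
                                         step = 1e5, sigFilter = TRUE) {
    repCols <- setdiff(names(expr), c("gene_id", "chrom", "tss"))
    nrep <- length(repCols)
    if (nrep < 2L) stop("need at least 2 replicates")
    if (sigFilter && nrep < 3L)
        stop("significance filtering needs at least 3 replicates")
    E <- as.matrix(expr[, repCols])
    keep <- rowSums(E > 0) >= 1L
    expr <- expr[keep, , drop = FALSE]
    E <- E[keep, , drop = FALSE]
    lab <- compartmentLabels(assignment)
    ids <- locateBins(assignment@bins, expr$chrom, expr$tss)
    geneLab <- ifelse(is.na(ids), NA_character_, lab[ids + 1L])

    # all same-chromosome pairs within maxDist, both genes labeled
    pairs <- do.call(rbind, lapply(split(seq_len(nrow(expr)), expr$chrom),
        function(ii) {
            if (length(ii) < 2L) return(NULL)
            cmb <- utils::combn(ii, 2L)
            data.frame(a = cmb[1L, ], b = cmb[2L, ])
        }))
    if (is.null(pairs) || !nrow(pairs)) stop("no same-chromosome gene pairs")
    pairs$dist <- abs(expr$tss[pairs$a] - expr$tss[pairs$b])
    pairs <- pairs[pairs$dist <= maxDist &
                   !is.na(geneLab[pairs$a]) & !is.na(geneLab[pairs$b]), ,
                   drop = FALSE]
    pairs$intra <- geneLab[pairs$a] == geneLab[pairs$b]
    stat <- t(vapply(seq_len(nrow(pairs)), function(r) {
        ct <- suppressWarnings(
            stats::cor.test(E[pairs$a[r], ], E[pairs$b[r], ],
                            method = "spearman"))
        c(ct$estimate, ct$p.value)
    }, numeric(2)))
    pairs$rho <- stat[, 1]
    pairs$p <- stat[, 2]
    pairs <- pairs[is.finite(pairs$rho), , drop = FALSE]

    grpMean <- function(sub) if (nrow(sub)) mean(sub$rho) else NA_real_
    out <- lapply(seq(step, maxDist, by = step), function(D) {
        sub <- pairs[pairs$dist <= D, , drop = FALSE]
        sig <- if (sigFilter) sub[!is.na(sub$p) & sub$p < 0.05, , drop = FALSE]
               else sub
        mi <- grpMean(sig[sig$intra, , drop = FALSE])
        me <- grpMean(sig[!sig$intra, , drop = FALSE])
        miA <- grpMean(sub[sub$intra, , drop = FALSE])
        meA <- grpMean(sub[!sub$intra, , drop = FALSE])
        data.frame(dist = D,
                   nIntra = sum(sub$intra), nInter = sum(!sub$intra),
                   meanIntra = mi, meanInter = me, ratio = mi / me,
                   meanIntraAll = miA, meanInterAll = meA,
                   ratioAll = miA / meA)
    })
    do.call(rbind, out)
}
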