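## External validation with ChIA-PET loops: BEDPE parsing/filtering,
## anchor-to-sub-compartment assignment, loop-compartment matrices,
## intra/inter loop ratios, and Fisher comparison between methods.

#' Construct a LoopSet, applying the standard filters
#'
#' Retains intra-chromosomal loops supported by at least \code{minPet}
#' paired-end tags; inter-chromosomal and low-support records are dropped
#' and counted.
#'
#' @param df data.frame with columns \code{chrom1,start1,end1,chrom2,
#'   start2,end2} (0-based half-open), optional \code{name}, and a PET
#'   count column.
#' @param minPet minimum PET support (default 5, inclusive).
#' @param petColumn index or name of the PET count column (default the
#'   BEDPE score column, column 8).
#' @return a \code{LoopSet}.
#' @export
loopSet <- function(df, minPet = 5L, petColumn = 8L) {
    if (ncol(df) < 7L) stop("BEDPE needs at least 7 columns")
    pet <- df[[petColumn]]
    if (!is.numeric(pet)) pet <- suppressWarnings(as.numeric(pet))
    if (any(is.na(pet)) || any(pet < 0))
        stop("malformed or negative PET count")
    lp <- data.frame(chrom1 = as.character(df[[1]]),
                     start1 = as.numeric(df[[2]]),
                     end1 = as.numeric(df[[3]]),
                     chrom2 = as.character(df[[4]]),
                     start2 = as.numeric(df[[5]]),
                     end2 = as.numeric(df[[6]]),
                     name = as.character(df[[7]]),
                     pet = pet)
    if (any(lp$start1 >= lp$end1 | lp$start2 >= lp$end2))
        stop("malformed anchor interval (start >= end)")
    inter <- lp$chrom1 != lp$chrom2
    low <- !inter & lp$pet < minPet
    out <- lp[!inter & !low, , drop = FALSE]
    rownames(out) <- NULL
    new("LoopSet", loops = out,
        counters = list(droppedInterChrom = sum(inter),
                        droppedLowSupport = sum(low),
                        minPet = minPet))
}

#' Read ChIA-PET loops from BEDPE
#'
#' Standard BEDPE (chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2), 0-based half-open, with the PET count in the score
#' column by default. Filtering as in \code{\link{loopSet}}.
#'
#' @param path BEDPE file.
#' @inheritParams loopSet
#' @return a \code{LoopSet}.
#' @export
readLoops <- function(path, minPet = 5L, petColumn = 8L) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
    loopSet(df, minPet = minPet, petColumn = petColumn)
}

#' Write a LoopSet as BEDPE
#'
#' @param loops a \code{LoopSet}.
#' @param path output path.
#' @export
writeLoops <- function(loops, path) {
    lp <- loopTable(loops)
    df <- data.frame(lp$chrom1, format(lp$start1, scientific = FALSE, trim = TRUE),
                     format(lp$end1, scientific = FALSE, trim = TRUE),
                     lp$chrom2, format(lp$start2, scientific = FALSE, trim = TRUE),
                     format(lp$end2, scientific = FALSE, trim = TRUE),
                     lp$name, lp$pet, ".", ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Assign a loop anchor to a sub-compartment
#'
#' For each label, the overlap ratio is the fraction of the anchor's base
#' pairs covered by bins carrying that label; the anchor is assigned to a
#' label iff its ratio exceeds 0.5 (strict, so an exact 50/50 split is
#' unassigned). Anchors outside the covered genome return NA with a
#' warning.
#'
#' @param chrom,start,end anchor interval(s), 0-based half-open
#'   (vectorized).
#' @param assignment a \code{SubCompartmentAssignment}.
#' @return character vector of labels or NA.
#' @export
assignAnchor <- function(chrom, start, end, assignment) {
    lab <- compartmentLabels(assignment)
    gr <- bins(assignment)
    q <- GRanges(chrom, IRanges(start = start + 1, end = end))
    hits <- suppressWarnings(findOverlaps(q, gr))
    out <- rep(NA_character_, length(q))
    if (!length(hits)) {
        if (length(q)) warning("anchor(s) outside the covered genome")
        return(out)
    }
    ov <- width(pintersect(q[queryHits(hits)], gr[subjectHits(hits)]))
    hitLab <- lab[subjectHits(hits)]
    keep <- !is.na(hitLab)
    df <- data.frame(q = queryHits(hits)[keep], lab = hitLab[keep],
                     bp = ov[keep])
    if (nrow(df)) {
        agg <- stats::aggregate(bp ~ q + lab, df, sum)
        agg$ratio <- agg$bp / (end - start)[agg$q]
        agg <- agg[agg$ratio > 0.5, , drop = FALSE]
        out[agg$q] <- agg$lab
    }
    covered <- unique(queryHits(hits))
    if (length(covered) < length(q))
        warning(length(q) - length(covered),
                " anchor(s) outside the covered genome")
    out
}

#' @rdname assignAnchor
#' @param loops a \code{LoopSet}.
#' @return \code{assignAnchors}: data.frame with columns \code{left},
#'   \code{right}.
#' @export
assignAnchors <- function(loops, assignment) {
    lp <- loopTable(loops)
    data.frame(
        left = assignAnchor(lp$chrom1, lp$start1, lp$end1, assignment),
        right = assignAnchor(lp$chrom2, lp$start2, lp$end2, assignment))
}

#' Loop-compartment count matrices
#'
#' Builds the k x k matrix M where \code{M[i, j]} counts loops with left
#' anchor in sub-compartment i and right anchor in j, the symmetrized
#' \code{Msym = M + t(M)}, and \code{Mnorm = Msym / sum(Msym)}. Loops with
#' an unassignable anchor are excluded and counted.
#'
#' @param loops a \code{LoopSet}.
#' @param assignment a \code{SubCompartmentAssignment}.
#' @return a \code{LoopCompartmentMatrix}.
#' @export
loopCompartmentMatrix <- function(loops, assignment) {
    k <- nCompartments(assignment)
    lv <- paste0("C", seq_len(k))
    an <- assignAnchors(loops, assignment)
    ok <- !is.na(an$left) & !is.na(an$right)
    if (!any(ok)) stop("no loop with both anchors assignable")
    tab <- table(factor(an$left[ok], levels = lv),
                 factor(an$right[ok], levels = lv))
    M <- matrix(as.numeric(tab), k, k, dimnames = list(lv, lv))
    Msym <- M + t(M)
    new("LoopCompartmentMatrix", M = M, Msym = Msym,
        Mnorm = Msym / sum(Msym),
        nIntra = as.integer(sum(an$left[ok] == an$right[ok])),
        nInter = as.integer(sum(an$left[ok] != an$right[ok])),
        nExcluded = as.integer(sum(!ok)))
}

#' Intra- vs inter-sub-compartment loop ratio
#'
#' A loop is intra when both anchors fall in the same sub-compartment and
#' inter otherwise; loops with an unassignable anchor enter neither count.
#' A high ratio means the annotation captures the preferential looping
#' within sub-compartments.
#'
#' @inheritParams loopCompartmentMatrix
#' @return list with \code{nIntra}, \code{nInter}, \code{ratio}
#'   (\code{Inf} with \code{infinite = TRUE} when no inter loop exists),
#'   and \code{nExcluded}.
#' @export
intraInterRatio <- function(loops, assignment) {
    an <- assignAnchors(loops, assignment)
    ok <- !is.na(an$left) & !is.na(an$right)
    if (!any(ok)) stop("no loop with both anchors assignable")
    nIntra <- sum(an$left[ok] == an$right[ok])
    nInter <- sum(an$left[ok] != an$right[ok])
    list(nIntra = nIntra, nInter = nInter,
         ratio = if (nInter == 0) Inf else nIntra / nInter,
         infinite = nInter == 0, nExcluded = sum(!ok))
}

#' Fisher comparison of two methods' loop ratios
#'
#' Two-sided Fisher exact test on the 2x2 table of (intra, inter) loop
#' counts from two annotations, asking whether method A concentrates loops
#' within its sub-compartments more than method B.
#'
#' @param nIntraA,nInterA,nIntraB,nInterB nonnegative counts.
#' @return list with \code{oddsRatio} (sample odds ratio) and two-sided
#'   \code{p}.
#' @export
fisherCompare <- function(nIntraA, nInterA, nIntraB, nInterB) {
    tab <- matrix(c(nIntraA, nInterA, nIntraB, nInterB), 2,
                  dimnames = list(c("intra", "inter"), c("A", "B")))
    if (any(tab < 0)) stop("counts must be nonnegative")
    if (any(rowSums(tab) == 0) && any(colSums(tab) == 0))
        stop("degenerate all-zero table")
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    or <- (nIntraA * nInterB) / (nInterA * nIntraB)
    list(oddsRatio = or, p = ft$p.value)
}
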