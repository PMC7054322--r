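#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols "mcols<-"
NULL

#' BinTable: a fixed-resolution partition of the genome
#'
#' A \code{BinTable} tiles every chromosome into consecutive bins of a fixed
#' width (the resolution); the last bin of a chromosome may be shorter. Each
#' bin carries a dense, 0-based integer \code{node_id} that indexes nodes of
#' the contact graph and rows of embedding matrices. Coordinates follow the
#' BED convention: 0-based, half-open.
#'
#' @slot bins a \code{GRanges} (1-based internally, as usual for
#'   \code{GRanges}) with an integer metadata column \code{node_id}.
#' @slot resolution bin width in bp.
#' @export
setClass("BinTable",
    representation(bins = "GRanges", resolution = "numeric"))

setValidity("BinTable", function(object) {
    gr <- object@bins
    msg <- character()
    if (length(object@resolution) != 1L || object@resolution <= 0)
        msg <- c(msg, "resolution must be a single positive number")
    if (!"node_id" %in% names(mcols(gr)))
        msg <- c(msg, "bins must carry a node_id metadata column")
    else {
        ids <- mcols(gr)$node_id
        if (length(ids) && !identical(sort(ids), seq_len(length(gr)) - 1L))
            msg <- c(msg, "node_id values must be contiguous from 0")
    }
    if (length(gr)) {
        if (any(width(gr) <= 0))
            msg <- c(msg, "all bins must have positive width")
        if (any(width(gr) > object@resolution))
            msg <- c(msg, "no bin may exceed the resolution")
    }
    if (length(msg)) msg else TRUE
})

#' ContactGraph: weighted inter-chromosomal interaction graph
#'
#' Undirected graph over genomic bins in which an edge (i, j) carries the
#' normalized Hi-C contact weight between bins on *different* chromosomes.
#' Every edge is stored once with \code{i < j}; all weights are strictly
#' positive. \code{totalWeight} is the sum of all edge weights and
#' \code{degree} the per-node sum of incident weights (the node strength).
#'
#' @slot bins the \code{BinTable} indexing the nodes.
#' @slot edges \code{data.frame} with integer columns \code{i}, \code{j}
#'   (0-based node ids, \code{i < j}) and numeric \code{w}.
#' @slot totalWeight sum of edge weights.
#' @slot degree numeric vector, one entry per bin (0 for isolated bins).
#' @slot counters list of parsing/bookkeeping counters (dropped intra-
#'   chromosomal records, dropped nonpositive weights, merged duplicates).
#' @export
setClass("ContactGraph",
    representation(bins = "BinTable", edges = "data.frame",
                   totalWeight = "numeric", degree = "numeric",
                   counters = "list"))

setValidity("ContactGraph", function(object) {
    ed <- object@edges
    msg <- character()
    n <- nBins(object@bins)
    if (!all(c("i", "j", "w") %in% names(ed)))
        msg <- c(msg, "edges must have columns i, j, w")
    else if (nrow(ed)) {
        if (any(ed$i >= ed$j)) msg <- c(msg, "edges must be stored with i < j")
        if (any(ed$i < 0 | ed$j >= n)) msg <- c(msg, "node ids out of range")
        if (any(!is.finite(ed$w)) || any(ed$w <= 0))
            msg <- c(msg, "all edge weights must be finite and positive")
        chrom <- as.character(seqnames(object@bins@bins))
        if (any(chrom[ed$i + 1L] == chrom[ed$j + 1L]))
            msg <- c(msg, "edges must join bins on different chromosomes")
    }
    if (length(object@degree) != n)
        msg <- c(msg, "degree must have one entry per bin")
    w <- if (nrow(ed)) sum(ed$w) else 0
    if (abs(object@totalWeight - w) > 1e-9 * max(1, w))
        msg <- c(msg, "totalWeight does not match the edge list")
    if (length(msg)) msg else TRUE
})

#' NodeEmbedding: low-dimensional node representations
#'
#' Holds the vertex vectors \eqn{u_i} (one row per embedded node) and, for
#' second-order or joint training, the context vectors \eqn{u'_i}. Row names
#' are the 0-based node ids of the embedded (connected) bins.
#'
#' @slot vertex numeric matrix, embedded nodes x dim.
#' @slot context numeric matrix with the same shape, or 0 rows when the
#'   embedding has no context half (pure first-order).
#' @slot mode one of "first", "second", "joint", "separate".
#' @slot metadata list (training configuration, initial matrices, update
#'   counters).
#' @export
setClass("NodeEmbedding",
    representation(vertex = "matrix", context = "matrix",
                   mode = "character", metadata = "list"))

setValidity("NodeEmbedding", function(object) {
    msg <- character()
    if (ncol(object@vertex) < 1L) msg <- c(msg, "embedding dim must be >= 1")
    if (any(!is.finite(object@vertex)))
        msg <- c(msg, "vertex vectors must be finite")
    if (nrow(object@context) && any(!is.finite(object@context)))
        msg <- c(msg, "context vectors must be finite")
    if (is.null(rownames(object@vertex)))
        msg <- c(msg, "vertex rows must be named by node id")
    if (length(msg)) msg else TRUE
})

#' SubCompartmentAssignment: bin-to-sub-compartment labels
#'
#' Maps every genomic bin to a sub-compartment label \code{C1..Ck}, or
#' \code{NA} for bins that cannot be assigned (no inter-chromosomal
#' contacts).
#'
#' @slot labels character vector, one per bin, values \code{C1..Ck} or NA.
#' @slot k number of sub-compartments.
#' @slot bins the \code{BinTable} the labels refer to.
#' @export
setClass("SubCompartmentAssignment",
    representation(labels = "character", k = "integer", bins = "BinTable"))

setValidity("SubCompartmentAssignment", function(object) {
    msg <- character()
    if (length(object@labels) != nBins(object@bins))
        msg <- c(msg, "one label (possibly NA) per bin required")
    lv <- unique(object@labels[!is.na(object@labels)])
    if (length(lv) && !all(grepl("^C[0-9]+$", lv)))
        msg <- c(msg, "labels must match ^C[0-9]+$ or be NA")
    if (length(lv) && object@k < length(lv))
        msg <- c(msg, "k smaller than the number of distinct labels")
    if (length(msg)) msg else TRUE
})

#' LoopSet: ChIA-PET loops
#'
#' Intra-chromosomal chromatin loops with their paired-end-tag (PET)
#' support, as read from BEDPE after filtering. Anchor coordinates are
#' 0-based half-open.
#'
#' @slot loops \code{data.frame} with columns \code{chrom1,start1,end1,
#'   chrom2,start2,end2,name,pet}.
#' @slot counters list of dropped-record counters (inter-chromosomal,
#'   low support).
#' @export
setClass("LoopSet",
    representation(loops = "data.frame", counters = "list"))

setValidity("LoopSet", function(object) {
    lp <- object@loops
    need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "pet")
    msg <- character()
    if (!all(need %in% names(lp)))
        msg <- c(msg, paste("loops must have columns",
                            paste(need, collapse = ", ")))
    else if (nrow(lp)) {
        if (any(lp$chrom1 != lp$chrom2))
            msg <- c(msg, "loop anchors must share a chromosome")
        if (any(lp$start1 >= lp$end1 | lp$start2 >= lp$end2))
            msg <- c(msg, "anchor intervals must satisfy start < end")
        if (any(lp$pet < 1))
            msg <- c(msg, "pet counts must be >= 1")
    }
    if (length(msg)) msg else TRUE
})

#' LoopCompartmentMatrix: loop counts between sub-compartments
#'
#' \code{M[i, j]} counts loops whose left anchor falls in sub-compartment i
#' and right anchor in j; \code{Msym = M + t(M)} removes the arbitrary
#' left/right orientation and \code{Mnorm = Msym / sum(Msym)} normalizes to
#' a probability table.
#'
#' @slot M,Msym,Mnorm k x k numeric matrices.
#' @slot nIntra,nInter,nExcluded loop counts: same-compartment,
#'   different-compartment, and excluded for an unassignable anchor.
#' @export
setClass("LoopCompartmentMatrix",
    representation(M = "matrix", Msym = "matrix", Mnorm = "matrix",
                   nIntra = "integer", nInter = "integer",
                   nExcluded = "integer"))

setValidity("LoopCompartmentMatrix", function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@Msym, t(object@Msym))))
        msg <- c(msg, "Msym must be symmetric")
    if (any(object@M < 0)) msg <- c(msg, "counts must be nonnegative")
    if (sum(object@Msym) > 0 &&
        abs(sum(object@Mnorm) - 1) > 1e-9)
        msg <- c(msg, "Mnorm entries must sum to 1")
    if (length(msg)) msg else TRUE
})
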