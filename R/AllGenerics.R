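#' @include AllClasses.R
NULL

#' Accessors for subHiC classes
#'
#' Standard accessors for the package's S4 containers: genomic bins,
#' resolution, edge list, total weight, node strength, embedding matrices
#' and sub-compartment labels.
#'
#' @param x a subHiC object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname accessors
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))

#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("totalWeight", function(x) standardGeneric("totalWeight"))

#' @rdname accessors
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' @rdname accessors
#' @export
setGeneric("vertexVectors", function(x) standardGeneric("vertexVectors"))

#' @rdname accessors
#' @export
setGeneric("contextVectors", function(x) standardGeneric("contextVectors"))

#' @rdname accessors
#' @export
setGeneric("embeddingMode", function(x) standardGeneric("embeddingMode"))

#' @rdname accessors
#' @export
setGeneric("compartmentLabels", function(x) standardGeneric("compartmentLabels"))

#' @rdname accessors
#' @export
setGeneric("nCompartments", function(x) standardGeneric("nCompartments"))

#' @rdname accessors
#' @export
setGeneric("loopTable", function(x) standardGeneric("loopTable"))

#' @rdname accessors
#' @param type which matrix to return: raw counts \code{"raw"}, the
#'   symmetrized counts \code{"sym"} or the normalized table \code{"norm"}.
#' @export
setGeneric("loopCounts", function(x, type = c("sym", "raw", "norm"))
    standardGeneric("loopCounts"))

## ---- accessor methods -------------------------------------------------

#' @rdname accessors
setMethod("bins", "BinTable", function(x) x@bins)
#' @rdname accessors
setMethod("bins", "ContactGraph", function(x) x@bins@bins)
#' @rdname accessors
setMethod("bins", "SubCompartmentAssignment", function(x) x@bins@bins)

#' @rdname accessors
setMethod("resolution", "BinTable", function(x) x@resolution)
#' @rdname accessors
setMethod("resolution", "ContactGraph", function(x) x@bins@resolution)

#' @rdname accessors
setMethod("nBins", "BinTable", function(x) length(x@bins))
#' @rdname accessors
setMethod("nBins", "ContactGraph", function(x) length(x@bins@bins))

#' @rdname accessors
setMethod("graphEdges", "ContactGraph", function(x) x@edges)

#' @rdname accessors
setMethod("totalWeight", "ContactGraph", function(x) x@totalWeight)

#' @rdname accessors
setMethod("nodeDegree", "ContactGraph", function(x) x@degree)

#' @rdname accessors
setMethod("vertexVectors", "NodeEmbedding", function(x) x@vertex)

#' @rdname accessors
setMethod("contextVectors", "NodeEmbedding", function(x) x@context)

#' @rdname accessors
setMethod("embeddingMode", "NodeEmbedding", function(x) x@mode)

#' @rdname accessors
setMethod("compartmentLabels", "SubCompartmentAssignment",
          function(x) x@labels)

#' @rdname accessors
setMethod("nCompartments", "SubCompartmentAssignment", function(x) x@k)

#' @rdname accessors
setMethod("loopTable", "LoopSet", function(x) x@loops)

#' @rdname accessors
setMethod("loopCounts", "LoopCompartmentMatrix", function(x, type = c("sym", "raw", "norm")) {
    switch(match.arg(type), raw = x@M, sym = x@Msym, norm = x@Mnorm)
})

## ---- show methods -----------------------------------------------------

#' @exportMethod show
setMethod("show", "BinTable", function(object) {
    chrom <- as.character(seqnames(object@bins))
    cat(sprintf("BinTable: %d bins over %d chromosome(s) at %g bp\n",
                length(object@bins), length(unique(chrom)),
                object@resolution))
})

setMethod("show", "ContactGraph", function(object) {
    cat(sprintf(paste0("ContactGraph: %d bins, %d inter-chromosomal edges, ",
                       "total weight %.4g\n"),
                nBins(object), nrow(object@edges), object@totalWeight))
    ct <- object@counters
    if (length(ct))
        cat(sprintf("  dropped: %d intra-chromosomal, %d nonpositive/NaN; %d duplicate records merged\n",
                    ct$droppedIntra %||% 0L, ct$droppedNonpositive %||% 0L,
                    ct$duplicatesMerged %||% 0L))
})

setMethod("show", "NodeEmbedding", function(object) {
    cat(sprintf("NodeEmbedding: %d nodes x %d dims (mode: %s%s)\n",
                nrow(object@vertex), ncol(object@vertex), object@mode,
                if (nrow(object@context)) ", with context vectors" else ""))
})

setMethod("show", "SubCompartmentAssignment", function(object) {
    tab <- table(factor(object@labels, levels = paste0("C", seq_len(object@k))),
                 useNA = "ifany")
    cat(sprintf("SubCompartmentAssignment: %d bins, k = %d (%d unassigned)\n",
                length(object@labels), object@k,
                sum(is.na(object@labels))))
    print(tab)
})

setMethod("show", "LoopSet", function(object) {
    cat(sprintf("LoopSet: %d intra-chromosomal loops (PET >= %s)\n",
                nrow(object@loops),
                object@counters$minPet %||% "?"))
    ct <- object@counters
    if (length(ct))
        cat(sprintf("  dropped: %d inter-chromosomal, %d low-support\n",
                    ct$droppedInterChrom %||% 0L, ct$droppedLowSupport %||% 0L))
})

setMethod("show", "LoopCompartmentMatrix", function(object) {
    cat(sprintf("LoopCompartmentMatrix: %d x %d, %d intra / %d inter loops (%d excluded)\n",
                nrow(object@M), ncol(object@M), object@nIntra, object@nInter,
                object@nExcluded))
    print(object@Msym)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
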