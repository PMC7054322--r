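## Bin tables, contact graphs, and the text formats around them.
## All coordinates on disk are 0-based half-open (BED convention).

FILE_HEADER_PREFIX <- "#subHiC"

fileHeader <- function(res) {
    sprintf("%s resolution=%g version=%s", FILE_HEADER_PREFIX, res,
            as.character(utils::packageVersion("subHiC")))
}

#' Build a bin table from a named vector of chromosome lengths
#'
#' @param seqlengths named numeric vector of chromosome lengths in bp.
#' @param resolution bin width in bp.
#' @return a \code{BinTable}; each chromosome is tiled into
#'   \code{ceiling(length/resolution)} bins, node ids assigned in input
#'   order then position order.
#' @export
binTableFromSeqlengths <- function(seqlengths, resolution) {
    if (length(resolution) != 1L || !is.finite(resolution) || resolution <= 0)
        stop("resolution must be a single positive number")
    if (is.null(names(seqlengths)) || any(names(seqlengths) == ""))
        stop("seqlengths must be named by chromosome")
    if (anyDuplicated(names(seqlengths)))
        stop("duplicate chromosome name in seqlengths")
    if (any(!is.finite(seqlengths)) || any(seqlengths <= 0))
        stop("all chromosome lengths must be positive")
    starts <- lapply(seqlengths, function(len) seq(0, len - 1, by = resolution))
    s0 <- unlist(starts, use.names = FALSE)
    chrom <- rep(names(seqlengths), lengths(starts))
    e0 <- pmin(s0 + resolution, rep(unname(seqlengths), lengths(starts)))
    gr <- GRanges(factor(chrom, levels = names(seqlengths)),
                  IRanges(start = s0 + 1, end = e0))
    mcols(gr)$node_id <- seq_along(gr) - 1L
    new("BinTable", bins = gr, resolution = as.numeric(resolution))
}

#' Load a bin table from a UCSC chrom.sizes file
#'
#' @param path two-column TAB file: chromosome name, length in bp.
#' @param resolution bin width in bp.
#' @return a \code{BinTable}.
#' @export
loadBinTable <- function(path, resolution) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "length"),
                            colClasses = c("character", "numeric"),
                            comment.char = "#")
    if (nrow(df) == 0L) stop("empty chrom.sizes file: ", path)
    sl <- stats::setNames(df$length, df$chrom)
    binTableFromSeqlengths(sl, resolution)
}

#' Map genomic positions to node ids
#'
#' @param binTable a \code{BinTable}.
#' @param chrom,pos chromosome names and 0-based positions.
#' @return integer vector of 0-based node ids (NA outside the covered
#'   genome).
#' @export
locateBins <- function(binTable, chrom, pos) {
    q <- GRanges(chrom, IRanges(start = pos + 1, width = 1))
    hits <- suppressWarnings(findOverlaps(q, bins(binTable)))
    out <- rep(NA_integer_, length(q))
    out[queryHits(hits)] <- mcols(bins(binTable))$node_id[subjectHits(hits)]
    out
}

#' Construct a contact graph from an edge table
#'
#' Applies the graph's cleaning rules: intra-chromosomal records are
#' dropped (counted), duplicate records (either orientation) are summed,
#' and zero/negative/non-finite weights are dropped with a warning count.
#'
#' @param binTable a \code{BinTable}.
#' @param i,j 0-based node ids.
#' @param w contact weights.
#' @return a \code{ContactGraph}.
#' @export
contactGraphFromEdges <- function(binTable, i, j, w) {
    n <- nBins(binTable)
    i <- as.integer(i); j <- as.integer(j); w <- as.numeric(w)
    if (any(is.na(i)) || any(is.na(j)) ||
        any(i < 0) || any(j < 0) || any(i >= n) || any(j >= n))
        stop("node id out of range [0, ", n - 1, "]")
    bad <- !is.finite(w) | w <= 0
    droppedNonpositive <- sum(bad)
    if (droppedNonpositive)
        warning(droppedNonpositive,
                " contact record(s) with zero/negative/non-finite weight dropped")
    i <- i[!bad]; j <- j[!bad]; w <- w[!bad]
    chrom <- as.character(seqnames(bins(binTable)))
    intra <- chrom[i + 1L] == chrom[j + 1L]
    droppedIntra <- sum(intra)
    if (droppedIntra)
        message(droppedIntra, " intra-chromosomal record(s) dropped")
    i <- i[!intra]; j <- j[!intra]; w <- w[!intra]
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- lo * n + hi
    dup <- duplicated(key)
    duplicatesMerged <- sum(dup)
    ws <- rowsum(w, key, reorder = TRUE)
    ukey <- sort(unique(key))
    ed <- data.frame(i = as.integer(ukey %/% n), j = as.integer(ukey %% n),
                     w = as.numeric(ws[, 1]))
    ed <- ed[order(ed$i, ed$j), , drop = FALSE]
    rownames(ed) <- NULL
    deg <- numeric(n)
    if (nrow(ed)) {
        add <- rowsum(c(ed$w, ed$w), c(ed$i, ed$j))
        deg[as.integer(rownames(add)) + 1L] <- add[, 1]
    }
    new("ContactGraph", bins = binTable, edges = ed,
        totalWeight = sum(ed$w), degree = deg,
        counters = list(droppedIntra = droppedIntra,
                        droppedNonpositive = droppedNonpositive,
                        duplicatesMerged = duplicatesMerged))
}

#' Load inter-chromosomal contacts from a sparse triplet file
#'
#' Two TAB-separated dialects are accepted: \code{node_i node_j weight}
#' with 0-based node ids from the bin table, or
#' \code{chrom1 start1 chrom2 start2 weight} where each start is a 0-based
#' bin start (a multiple of the resolution, except in the last bin).
#' Intra-chromosomal entries are dropped and counted, duplicate records in
#' either orientation are summed, and nonpositive weights are dropped with
#' a warning.
#'
#' @param path triplet file.
#' @param binTable a \code{BinTable}.
#' @return a \code{ContactGraph}.
#' @export
loadContacts <- function(path, binTable) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#",
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L)
        return(contactGraphFromEdges(binTable, integer(), integer(), numeric()))
    if (ncol(df) == 3L) {
        i <- df[[1]]; j <- df[[2]]; w <- df[[3]]
        if (!is.numeric(i) || !is.numeric(j) || !is.numeric(w))
            stop("malformed triplet line in ", path)
    } else if (ncol(df) == 5L) {
        res <- resolution(binTable)
        offL <- df[[2]] %% res
        offR <- df[[4]] %% res
        if (any(offL != 0) || any(offR != 0))
            stop("coordinate-dialect start not a multiple of the resolution")
        i <- locateBins(binTable, df[[1]], df[[2]])
        j <- locateBins(binTable, df[[3]], df[[4]])
        if (any(is.na(i)) || any(is.na(j)))
            stop("contact coordinate outside the covered genome")
        w <- df[[5]]
    } else stop("expected 3 or 5 TAB-separated columns, got ", ncol(df))
    contactGraphFromEdges(binTable, i, j, w)
}

#' Write a contact graph as a node-id triplet file
#'
#' @param graph a \code{ContactGraph}.
#' @param path output path.
#' @export
writeContacts <- function(graph, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(fileHeader(resolution(graph)), con)
    ed <- graphEdges(graph)
    if (nrow(ed))
        utils::write.table(format(ed, scientific = FALSE, trim = TRUE),
                           con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a bin table as a chrom.sizes file
#'
#' @param binTable a \code{BinTable}.
#' @param path output path.
#' @export
writeChromSizes <- function(binTable, path) {
    gr <- bins(binTable)
    chrom <- as.character(seqnames(gr))
    len <- tapply(end(gr), chrom, max)
    len <- len[unique(chrom)]          # preserve original order
    utils::write.table(data.frame(names(len), as.integer(len)), path,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Nodes with at least one inter-chromosomal contact
#'
#' Bins with zero inter-chromosomal degree cannot be embedded; they are
#' reported as unassignable and labeled NA downstream.
#'
#' @param graph a \code{ContactGraph}.
#' @return sorted integer vector of 0-based node ids with degree > 0.
#' @export
connectedNodes <- function(graph) {
    which(nodeDegree(graph) > 0) - 1L
}

#' Construct a sub-compartment assignment
#'
#' @param labels character vector of \code{C1..Ck} labels (NA allowed), one
#'   per bin.
#' @param binTable the \code{BinTable} the labels refer to.
#' @param k number of sub-compartments; defaults to the number of distinct
#'   labels present.
#' @return a \code{SubCompartmentAssignment}.
#' @export
subCompartmentAssignment <- function(labels, binTable, k = NULL) {
    labels <- as.character(labels)
    if (is.null(k)) {
        present <- unique(labels[!is.na(labels)])
        k <- if (length(present))
            max(as.integer(sub("^C", "", present))) else 0L
    }
    new("SubCompartmentAssignment", labels = labels, k = as.integer(k),
        bins = binTable)
}

#' Write / read a sub-compartment assignment as BED4
#'
#' One line per bin: chrom, start, end (0-based half-open) and the label
#' (\code{C1..Ck} or \code{NA}). \code{readAssignments(writeAssignments(x))}
#' round-trips exactly.
#'
#' @param assignment a \code{SubCompartmentAssignment}.
#' @param path file path.
#' @export
writeAssignments <- function(assignment, path) {
    lab <- compartmentLabels(assignment)
    ok <- is.na(lab) | grepl("^C[0-9]+$", lab)
    if (!all(ok)) stop("labels must match ^C[0-9]+$ or be NA")
    gr <- bins(assignment)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(fileHeader(assignment@bins@resolution), con)
    if (length(gr)) {
        df <- data.frame(chrom = as.character(seqnames(gr)),
                         start = start(gr) - 1L, end = end(gr),
                         label = ifelse(is.na(lab), "NA", lab))
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' @rdname writeAssignments
#' @param binTable optional \code{BinTable}; reconstructed from the BED
#'   intervals and the header resolution when omitted.
#' @export
readAssignments <- function(path, binTable = NULL) {
    header <- readLines(path, n = 1L)
    res <- NA_real_
    if (length(header) && startsWith(header, FILE_HEADER_PREFIX))
        res <- as.numeric(sub(".*resolution=([0-9.eE+-]+).*", "\\1", header))
    df <- tryCatch(
        utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "label"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character")),
        error = function(e) data.frame(chrom = character(),
                                       start = numeric(), end = numeric(),
                                       label = character()))
    lab <- df$label
    lab[lab == "NA"] <- NA_character_
    bad <- !is.na(lab) & !grepl("^C[0-9]+$", lab)
    if (any(bad)) stop("invalid label(s): ", paste(unique(lab[bad]), collapse = ", "))
    if (is.null(binTable)) {
        if (nrow(df) == 0L) {
            if (is.na(res)) res <- 1
            gr0 <- GRanges(character(), IRanges())
            mcols(gr0)$node_id <- integer()
            binTable <- new("BinTable", bins = gr0, resolution = res)
        } else {
            if (is.na(res)) res <- max(df$end - df$start)
            sl <- tapply(df$end, df$chrom, max)[unique(df$chrom)]
            binTable <- binTableFromSeqlengths(
                stats::setNames(as.numeric(sl), names(sl)), res)
        }
    }
    out <- rep(NA_character_, nBins(binTable))
    if (nrow(df)) {
        ids <- locateBins(binTable, df$chrom, df$start)
        if (any(is.na(ids))) stop("BED interval outside the bin table")
        out[ids + 1L] <- lab
    }
    subCompartmentAssignment(out, binTable)
}

#' Write / read a node embedding as TSV
#'
#' Format: a header line \code{#dim=<d> mode=<m>}, then one row per node:
#' node id followed by the vector components (vertex vectors only; context
#' vectors are a training device, not part of the representation).
#'
#' @param embedding a \code{NodeEmbedding}.
#' @param path file path.
#' @export
writeEmbedding <- function(embedding, path) {
    V <- vertexVectors(embedding)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#dim=%d mode=%s", ncol(V), embeddingMode(embedding)),
               con)
    df <- data.frame(node_id = rownames(V),
                     format(V, digits = 17, scientific = TRUE, trim = TRUE))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
    header <- readLines(path, n = 1L)
    mode <- sub(".*mode=([a-z]+).*", "\\1", header)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
    V <- as.matrix(df[, -1, drop = FALSE])
    dimnames(V) <- list(as.character(df[[1]]), NULL)
    new("NodeEmbedding", vertex = V,
        context = matrix(numeric(), 0, ncol(V)),
        mode = mode, metadata = list())
}
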