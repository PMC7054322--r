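## End-to-end workflow: contacts -> graph -> embedding -> k-means ->
## relabel -> evaluation, with a machine-readable manifest for
## reproducibility.

#' Predict sub-compartments from a contact graph
#'
#' Runs the core method: LINE embedding of the inter-chromosomal contact
#' graph followed by k-means over the node vectors. \code{k = "auto"}
#' selects the number of sub-compartments by the gap statistic.
#'
#' @param graph a \code{ContactGraph}.
#' @param k number of sub-compartments, or \code{"auto"}.
#' @param config a \code{\link{trainingConfig}}.
#' @param kMin,kMax,B gap-statistic search range and reference count (only
#'   with \code{k = "auto"}).
#' @param nInit k-means restarts.
#' @param seed seed for clustering (training uses \code{config$seed}).
#' @return list with \code{embedding}, \code{assignment}, and \code{gap}
#'   (NULL unless \code{k = "auto"}).
#' @export
predictSubcompartments <- function(graph, k = 5L,
                                   config = trainingConfig(),
                                   kMin = 2L, kMax = 12L, B = 10L,
                                   nInit = 10L, seed = config$seed) {
    emb <- trainEmbedding(graph, config)
    gap <- NULL
    if (identical(k, "auto")) {
        gap <- gapStatistic(emb, kMin = 1L, kMax = kMax, B = B, seed = seed)
        k <- max(gap$chosenK, kMin)
    }
    asg <- kmeansCluster(emb, k = k, binTable = graph@bins, seed = seed,
                         nInit = nInit)
    list(embedding = emb, assignment = asg, gap = gap)
}

#' Run the full pipeline from files
#'
#' Loads bins and contacts, trains the embedding, clusters, optionally
#' relabels by a signal track, evaluates, and writes the assignment BED,
#' the embedding TSV, an evaluation JSON and a manifest recording inputs,
#' parameters and versions. Outputs are removed again if any stage fails.
#'
#' @param contactsPath sparse contact triplet file.
#' @param chromSizesPath UCSC chrom.sizes file.
#' @param resolution bin width in bp.
#' @param outDir output directory (created if missing).
#' @param k number of sub-compartments or \code{"auto"}.
#' @param config a \code{\link{trainingConfig}}.
#' @param signalTrack optional bedGraph used to order labels (open
#'   chromatin first); without it cluster numbering is arbitrary.
#' @param seed clustering seed.
#' @return (invisibly) the result of \code{\link{predictSubcompartments}}
#'   plus \code{evaluation} and the output paths.
#' @export
runPipeline <- function(contactsPath, chromSizesPath, resolution = 1e5,
                        outDir = ".", k = 5L, config = trainingConfig(),
                        signalTrack = NULL, seed = config$seed) {
    for (p in c(contactsPath, chromSizesPath))
        if (!file.exists(p)) stop("input file not found: ", p)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    outputs <- file.path(outDir, c("subcompartments.bed", "embedding.tsv",
                                   "evaluation.json", "manifest.json",
                                   "gap.tsv"))
    ok <- FALSE
    on.exit(if (!ok) unlink(outputs))

    bt <- loadBinTable(chromSizesPath, resolution)
    graph <- loadContacts(contactsPath, bt)
    res <- predictSubcompartments(graph, k = k, config = config,
                                  seed = seed)
    asg <- res$assignment
    if (!is.null(signalTrack)) {
        sig <- aggregateSignal(signalTrack, bt)
        asg <- relabelAssignment(
            asg, stats::setNames(sig$signal, sig$node_id))
    }
    ev <- evaluateAssignment(res$embedding, asg, graph)
    writeAssignments(asg, outputs[1])
    writeEmbedding(res$embedding, outputs[2])
    jsonlite::write_json(
        list(meanSilhouette = ev$silhouette$mean, daviesBouldin = ev$dbi,
             k = nCompartments(asg),
             nUnassigned = sum(is.na(compartmentLabels(asg)))),
        outputs[3], auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
        list(package = "subHiC",
             version = as.character(utils::packageVersion("subHiC")),
             rVersion = R.version.string,
             inputs = list(contacts = normalizePath(contactsPath),
                           chromSizes = normalizePath(chromSizesPath)),
             parameters = list(resolution = resolution, k = k,
                               config = unclass(config), seed = seed),
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
        outputs[4], auto_unbox = TRUE, digits = NA)
    if (!is.null(res$gap))
        utils::write.table(res$gap$table, outputs[5], sep = "\t",
                           quote = FALSE, row.names = FALSE)
    ok <- TRUE
    invisible(c(res, list(assignment = asg, evaluation = ev,
                          outputs = outputs)))
}
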