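## Structural evaluation of a sub-compartment assignment: silhouette, the
## pairwise Davies-Bouldin variant, and intra-sub-compartment network
## topology (closeness, betweenness, weighted clustering coefficient).

#' Silhouette index
#'
#' Per-point \eqn{s_i = (b_i - a_i) / \max(a_i, b_i)} with Euclidean
#' distances: \eqn{a_i} is the mean distance to the point's own cluster
#' (excluding itself) and \eqn{b_i} the lowest mean distance to any other
#' cluster. Points in singleton clusters score 0, as do points with
#' \eqn{a_i = b_i = 0}.
#'
#' @param points numeric matrix (points x features).
#' @param labels cluster labels, one per point; at least two non-empty
#'   clusters.
#' @return list with per-point \code{s} and \code{mean}.
#' @export
silhouetteScore <- function(points, labels) {
    points <- as.matrix(points)
    labels <- as.character(labels)
    lv <- unique(labels)
    if (length(lv) < 2L) stop("silhouette needs at least two clusters")
    D <- as.matrix(stats::dist(points))
    n <- nrow(D)
    sizes <- table(labels)[lv]
    meanTo <- vapply(lv, function(l)
        rowSums(D[, labels == l, drop = FALSE]), numeric(n))
    # meanTo[i, c]: sum of distances from i to cluster c
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- labels[i]
        nOwn <- sizes[[own]]
        if (nOwn == 1L) { s[i] <- 0; next }
        a <- meanTo[i, own] / (nOwn - 1L)
        b <- min(meanTo[i, setdiff(lv, own)] /
                 unlist(sizes[setdiff(lv, own)]))
        s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    list(s = s, mean = mean(s))
}

#' Pairwise Davies-Bouldin index
#'
#' \eqn{DBI = (1/k) \sum_i \max_{j \ne i} (d_i + d_j) / d_{ij}} where
#' \eqn{d_i} is the mean distance over all point pairs *within* cluster i
#' (0 for singletons) and \eqn{d_{ij}} the mean distance over all pairs
#' *between* clusters i and j. Note this pairwise form differs from the
#' classic centroid-based index. Lower is better.
#'
#' @inheritParams silhouetteScore
#' @return the index (>= 0).
#' @export
daviesBouldinIndex <- function(points, labels) {
    points <- as.matrix(points)
    labels <- as.character(labels)
    lv <- sort(unique(labels))
    k <- length(lv)
    if (k < 2L) stop("Davies-Bouldin needs at least two clusters")
    D <- as.matrix(stats::dist(points))
    idx <- lapply(lv, function(l) which(labels == l))
    within <- vapply(idx, function(ii) {
        if (length(ii) < 2L) return(0)
        mean(D[ii, ii][upper.tri(D[ii, ii])])
    }, numeric(1))
    ratio <- matrix(NA_real_, k, k)
    for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
        between <- mean(D[idx[[a]], idx[[b]]])
        if (between == 0)
            stop("coincident clusters: between-cluster distance is zero")
        ratio[a, b] <- ratio[b, a] <- (within[a] + within[b]) / between
    }
    mean(apply(ratio, 1, max, na.rm = TRUE))
}

## ---- network topology -------------------------------------------------

# igraph view of a contact (sub)graph over an explicit vertex set
asIgraph <- function(graph, nodes = NULL) {
    if (is.null(nodes)) nodes <- seq_len(nBins(graph)) - 1L
    ed <- graphEdges(graph)
    ed <- ed[ed$i %in% nodes & ed$j %in% nodes, , drop = FALSE]
    igraph::graph_from_data_frame(
        data.frame(from = as.character(ed$i), to = as.character(ed$j),
                   weight = ed$w),
        directed = FALSE, vertices = data.frame(name = as.character(nodes)))
}

edgeDistances <- function(g, mode) {
    switch(mode, hop = NA, invweight = 1 / igraph::E(g)$weight)
}

#' Induced subgraph of one sub-compartment
#'
#' Restricts the contact graph to the bins carrying a given label; edges
#' retain their weights. The result shares the full bin table; the member
#' node ids are attached as \code{attr(, "nodes")} and are what the
#' centrality functions should be run over.
#'
#' @param graph a \code{ContactGraph}.
#' @param assignment a \code{SubCompartmentAssignment} over the same bins.
#' @param label a label present in the assignment, e.g. \code{"C1"}.
#' @return a \code{ContactGraph}.
#' @export
compartmentSubgraph <- function(graph, assignment, label) {
    lab <- compartmentLabels(assignment)
    if (!label %in% lab) stop("unknown label: ", label)
    keep <- which(!is.na(lab) & lab == label) - 1L
    ed <- graphEdges(graph)
    ed <- ed[ed$i %in% keep & ed$j %in% keep, , drop = FALSE]
    rownames(ed) <- NULL
    deg <- numeric(nBins(graph))
    if (nrow(ed)) {
        add <- rowsum(c(ed$w, ed$w), c(ed$i, ed$j))
        deg[as.integer(rownames(add)) + 1L] <- add[, 1]
    }
    out <- new("ContactGraph", bins = graph@bins, edges = ed,
               totalWeight = sum(ed$w), degree = deg, counters = list())
    attr(out, "nodes") <- keep
    out
}

graphNodeSet <- function(graph, nodes) {
    if (!is.null(nodes)) return(as.integer(nodes))
    att <- attr(graph, "nodes")
    if (!is.null(att)) as.integer(att) else seq_len(nBins(graph)) - 1L
}

#' Closeness centrality
#'
#' \eqn{C(u) = (n_u - 1) / \sum_v d(v, u)} within u's connected component,
#' scaled by the component fraction \eqn{(n_u - 1)/(n - 1)}
#' (Wasserman-Faust), which harmonizes disconnected graphs and reduces to
#' the plain definition on connected ones. Path length is 1 per edge in
#' \code{"hop"} mode or \eqn{1/w_{ij}} in \code{"invweight"} mode (strong
#' contacts are short).
#'
#' @param graph a \code{ContactGraph}.
#' @param mode \code{"hop"} (default) or \code{"invweight"}.
#' @param nodes vertex set (0-based node ids); defaults to the subgraph's
#'   member nodes or all bins.
#' @return named numeric vector, one value per node (0 for isolated
#'   nodes).
#' @export
closenessCentrality <- function(graph, mode = c("hop", "invweight"),
                                nodes = NULL) {
    mode <- match.arg(mode)
    nodes <- graphNodeSet(graph, nodes)
    if (!length(nodes)) stop("empty vertex set")
    g <- asIgraph(graph, nodes)
    D <- igraph::distances(g, weights = edgeDistances(g, mode))
    n <- length(nodes)
    out <- vapply(seq_len(n), function(u) {
        d <- D[, u]
        reach <- is.finite(d) & seq_len(n) != u
        nu <- sum(reach) + 1L
        if (nu < 2L) return(0)
        ((nu - 1) / (n - 1)) * ((nu - 1) / sum(d[reach]))
    }, numeric(1))
    stats::setNames(out, as.character(nodes))
}

#' Betweenness centrality
#'
#' \eqn{C_B(u) = \sum_{s \ne t \ne u} \sigma(s, t | u) / \sigma(s, t)}:
#' the fraction of shortest paths between other node pairs passing through
#' u, each unordered pair counted once, endpoints excluded. Unnormalized
#' by default; \code{normalized = TRUE} divides by \eqn{(n-1)(n-2)/2}.
#'
#' @inheritParams closenessCentrality
#' @param normalized divide by the number of node pairs.
#' @return named numeric vector per node.
#' @export
betweennessCentrality <- function(graph, mode = c("hop", "invweight"),
                                  nodes = NULL, normalized = FALSE) {
    mode <- match.arg(mode)
    nodes <- graphNodeSet(graph, nodes)
    if (!length(nodes)) stop("empty vertex set")
    g <- asIgraph(graph, nodes)
    b <- igraph::betweenness(g, directed = FALSE,
                             weights = edgeDistances(g, mode))
    n <- length(nodes)
    if (normalized && n > 2L) b <- b / ((n - 1) * (n - 2) / 2)
    stats::setNames(as.numeric(b), as.character(nodes))
}

#' Weighted clustering coefficient (Barrat)
#'
#' \eqn{c_u = \frac{1}{s_u (k_u - 1)} \sum_{v \ne w} \frac{w_{uv} +
#' w_{uw}}{2}} over ordered neighbor pairs (v, w) that close a triangle
#' with u, where \eqn{s_u} is the node strength and \eqn{k_u} its degree;
#' nodes with fewer than two neighbors score 0. Reduces to the ordinary
#' closed-triplet ratio on unit weights.
#'
#' @inheritParams closenessCentrality
#' @return named numeric vector in [0, 1] per node.
#' @export
clusteringCoefficients <- function(graph, nodes = NULL) {
    nodes <- graphNodeSet(graph, nodes)
    if (!length(nodes)) stop("empty vertex set")
    g <- asIgraph(graph, nodes)
    cc <- suppressWarnings(
        igraph::transitivity(g, type = "barrat", isolates = "zero"))
    cc[is.na(cc)] <- 0
    stats::setNames(as.numeric(cc), as.character(nodes))
}

#' Compare a metric between two methods (Mann-Whitney)
#'
#' Two-sided Wilcoxon rank-sum test between two samples of a per-node
#' metric (one sample per method), with the exact null distribution when
#' both samples are small (n <= 8) and tie-free, and the tie-corrected
#' normal approximation otherwise. \code{delta} is the difference of
#' sample medians (A - B).
#'
#' @param a,b numeric vectors of metric values.
#' @return list with \code{delta}, \code{U} (statistic for sample a), and
#'   two-sided \code{p}.
#' @export
compareMethods <- function(a, b) {
    if (!length(a) || !length(b)) stop("empty sample")
    exact <- length(a) <= 8L && length(b) <= 8L &&
        !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = !exact))
    list(delta = stats::median(a) - stats::median(b),
         U = unname(wt$statistic), p = wt$p.value)
}

#' Full structural evaluation of an assignment
#'
#' Computes the silhouette index and pairwise Davies-Bouldin index of the
#' labeled embedding and, per sub-compartment, the topology of its induced
#' inter-chromosomal subgraph: weighted clustering coefficient, closeness
#' and betweenness centrality.
#'
#' @param embedding a \code{NodeEmbedding} (or matrix with node-id row
#'   names).
#' @param assignment a \code{SubCompartmentAssignment}.
#' @param graph the \code{ContactGraph}; omit to skip topology metrics.
#' @param mode shortest-path mode for centralities, see
#'   \code{\link{closenessCentrality}}.
#' @return list of class \code{EvaluationReport}: \code{silhouette}
#'   (per-node and mean), \code{dbi}, and per-compartment topology tables.
#' @export
evaluateAssignment <- function(embedding, assignment, graph = NULL,
                               mode = c("hop", "invweight")) {
    mode <- match.arg(mode)
    V <- if (is(embedding, "NodeEmbedding")) vertexVectors(embedding)
         else as.matrix(embedding)
    lab <- compartmentLabels(assignment)
    labV <- lab[as.integer(rownames(V)) + 1L]
    keep <- !is.na(labV)
    sil <- silhouetteScore(V[keep, , drop = FALSE], labV[keep])
    dbi <- daviesBouldinIndex(V[keep, , drop = FALSE], labV[keep])
    topo <- NULL
    if (!is.null(graph)) {
        topo <- lapply(sort(unique(labV[keep])), function(l) {
            sub <- compartmentSubgraph(graph, assignment, l)
            data.frame(label = l, node_id = attr(sub, "nodes"),
                       closeness = unname(closenessCentrality(sub, mode)),
                       betweenness = unname(betweennessCentrality(sub, mode)),
                       clustCoef = unname(clusteringCoefficients(sub)))
        })
        topo <- do.call(rbind, topo)
    }
    structure(list(silhouette = sil, dbi = dbi, topology = topo,
                   labels = labV), class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
    cat(sprintf("mean silhouette %.4f | Davies-Bouldin %.4f\n",
                x$silhouette$mean, x$dbi))
    if (!is.null(x$topology)) {
        agg <- stats::aggregate(
            x$topology[c("closeness", "betweenness", "clustCoef")],
            by = list(label = x$topology$label), FUN = mean)
        print(agg, digits = 4)
    }
    invisible(x)
}
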