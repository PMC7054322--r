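## k-means over node embeddings, gap-statistic model selection, and
## canonical relabeling of sub-compartments.

#' k-means with k-means++ seeding, best of several restarts
#'
#' Euclidean k-means (Lloyd iterations via \code{stats::kmeans}) started
#' from k-means++ centers; the restart with the lowest within-cluster sum
#' of squares wins, ties going to the earliest restart. Deterministic given
#' \code{seed}.
#'
#' @param x numeric matrix (points x features).
#' @param k number of clusters (1 <= k <= nrow(x)).
#' @param seed integer seed.
#' @param nInit number of restarts.
#' @return list with \code{cluster} (integer labels 1..k), \code{centers},
#'   and \code{inertia} (total within-cluster sum of squares).
#' @export
kmeansFit <- function(x, k, seed = 1L, nInit = 10L) {
    x <- as.matrix(x)
    if (k < 1L) stop("k must be >= 1")
    if (k > nrow(x)) stop("k exceeds the number of points")
    if (k == 1L) {
        ctr <- matrix(colMeans(x), 1L)
        return(list(cluster = rep(1L, nrow(x)), centers = ctr,
                    inertia = sum(sweep(x, 2, ctr[1L, ])^2)))
    }
    best <- NULL
    for (r in seq_len(nInit)) {
        centers <- kmeansPlusPlus(x, k, seed + r - 1L)
        fit <- suppressWarnings(
            stats::kmeans(x, centers = centers, iter.max = 100L,
                          algorithm = "Lloyd"))
        if (is.null(best) || fit$tot.withinss < best$tot.withinss)
            best <- fit
    }
    list(cluster = as.integer(best$cluster), centers = best$centers,
         inertia = best$tot.withinss)
}

# k-means++ center selection (Arthur & Vassilvitskii): each next center is
# drawn with probability proportional to the squared distance to the
# nearest center already chosen.
kmeansPlusPlus <- function(x, k, seed) {
    n <- nrow(x)
    set.seed(seed)
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
    for (c in seq_len(k - 1L) + 1L) {
        if (all(d2 == 0)) idx <- sample.int(n, 1L)
        else idx <- sample.int(n, 1L, prob = d2)
        centers[c, ] <- x[idx, ]
        d2 <- pmin(d2, rowSums(sweep(x, 2, centers[c, ])^2))
    }
    # de-duplicate coincident centers by jittering towards distinct points
    centers
}

#' Cluster an embedding into sub-compartments
#'
#' Runs \code{\link{kmeansFit}} on the vertex vectors and returns a
#' \code{SubCompartmentAssignment}: embedded bins get provisional labels
#' \code{C1..Ck} (in arbitrary cluster order until
#' \code{\link{relabelAssignment}}), bins without inter-chromosomal
#' contacts get NA.
#'
#' @param embedding a \code{NodeEmbedding} (or matrix with node-id row
#'   names).
#' @param k number of sub-compartments (default 5).
#' @param binTable the \code{BinTable} behind the node ids.
#' @param seed,nInit passed to \code{\link{kmeansFit}}.
#' @return a \code{SubCompartmentAssignment}.
#' @export
kmeansCluster <- function(embedding, k = 5L, binTable, seed = 1L,
                          nInit = 10L) {
    V <- if (is(embedding, "NodeEmbedding")) vertexVectors(embedding)
         else as.matrix(embedding)
    fit <- kmeansFit(V, k, seed = seed, nInit = nInit)
    labels <- rep(NA_character_, nBins(binTable))
    ids <- as.integer(rownames(V))
    labels[ids + 1L] <- paste0("C", fit$cluster)
    out <- subCompartmentAssignment(labels, binTable, k = k)
    attr(out, "inertia") <- fit$inertia
    out
}

#' Gap-statistic selection of the number of sub-compartments
#'
#' Tibshirani's gap statistic: for each k, the log within-cluster
#' dispersion of the data is compared against B reference data sets drawn
#' uniformly in the principal-component-aligned bounding box of the data
#' (\code{cluster::clusGap} with \code{spaceH0 = "scaledPCA"}). The chosen
#' k is the smallest k with \eqn{gap(k) \ge gap(k+1) - s_{k+1}}.
#'
#' @param embedding a \code{NodeEmbedding} or numeric matrix.
#' @param kMin,kMax inclusive range of k to score.
#' @param B number of reference data sets (>= 2).
#' @param seed integer seed.
#' @param nInit restarts per k-means fit.
#' @return list of class \code{GapResult}: \code{table} (k, logW, ElogW,
#'   gap, SE) and \code{chosenK}.
#' @export
gapStatistic <- function(embedding, kMin = 1L, kMax = 10L, B = 10L,
                         seed = 1L, nInit = 5L) {
    V <- if (is(embedding, "NodeEmbedding")) vertexVectors(embedding)
         else as.matrix(embedding)
    if (kMin < 1L || kMax <= kMin) stop("need 1 <= kMin < kMax")
    if (B < 2L) stop("B must be >= 2")
    if (nrow(unique(V)) < 2L) stop("degenerate embedding: all points identical")
    set.seed(seed)
    fun <- function(x, k) list(cluster = kmeansFit(x, k, seed = seed,
                                                   nInit = nInit)$cluster)
    cg <- cluster::clusGap(V, FUNcluster = fun, K.max = kMax, B = B,
                           d.power = 2, spaceH0 = "scaledPCA",
                           verbose = FALSE)
    tab <- as.data.frame(cg$Tab)
    tab$k <- seq_len(nrow(tab))
    tab <- tab[tab$k >= kMin, c("k", "logW", "E.logW", "gap", "SE.sim")]
    names(tab) <- c("k", "logW", "ElogW", "gap", "SE")
    rownames(tab) <- NULL
    chosen <- tab$k[cluster::maxSE(tab$gap, tab$SE,
                                   method = "Tibs2001SEmax")]
    structure(list(table = tab, chosenK = as.integer(chosen), B = B),
              class = "GapResult")
}

#' @export
print.GapResult <- function(x, ...) {
    cat(sprintf("Gap statistic over k = %d..%d (B = %d): chosen k = %d\n",
                min(x$table$k), max(x$table$k), x$B, x$chosenK))
    print(x$table, digits = 4)
    invisible(x)
}

#' Relabel sub-compartments by a per-bin signal
#'
#' Renames clusters \code{C1..Ck} in decreasing order of mean signal
#' (e.g. gene density or chromatin accessibility), so that low indices
#' correspond to open chromatin. Ties are broken in favor of the larger
#' cluster. The partition itself is unchanged.
#'
#' @param assignment a \code{SubCompartmentAssignment}.
#' @param signal named numeric vector: names are 0-based node ids (or a
#'   plain vector with one value per bin); NA-signal bins are ignored.
#' @return the relabeled \code{SubCompartmentAssignment}, with the
#'   old-to-new permutation in \code{attr(, "permutation")}.
#' @export
relabelAssignment <- function(assignment, signal) {
    lab <- compartmentLabels(assignment)
    n <- length(lab)
    if (is.null(names(signal))) {
        if (length(signal) != n)
            stop("unnamed signal must have one value per bin")
        sig <- signal
    } else {
        sig <- rep(NA_real_, n)
        sig[as.integer(names(signal)) + 1L] <- signal
    }
    present <- sort(unique(lab[!is.na(lab)]))
    means <- vapply(present, function(l)
        mean(sig[!is.na(lab) & lab == l], na.rm = TRUE), numeric(1))
    if (any(is.nan(means)))
        stop("cluster(s) without signal coverage: ",
             paste(present[is.nan(means)], collapse = ", "))
    sizes <- vapply(present, function(l) sum(lab == l, na.rm = TRUE),
                    numeric(1))
    ord <- order(-means, -sizes)
    newName <- stats::setNames(paste0("C", seq_along(present)), present[ord])
    out <- subCompartmentAssignment(
        ifelse(is.na(lab), NA_character_, unname(newName[lab])),
        assignment@bins, k = assignment@k)
    attr(out, "permutation") <- newName
    out
}
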