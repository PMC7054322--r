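## LINE embedding of the inter-chromosomal contact graph: first-order and
## second-order proximity objectives, alias-method samplers, and the
## negative-sampling SGD wrappers around the compiled training loop.

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -35), 35)))

#' Training configuration for the LINE embedding
#'
#' Defaults follow the grid-selected values used for sub-compartment
#' calling: embedding size 100, 5 negative samples per positive draw, and
#' 25 million edge samples. \code{samples} is interpreted in millions by
#' default (the scale of the published grid \code{15, 20, 25, 30, 40, 50});
#' set \code{samplesUnit = "absolute"} to pass a raw draw count.
#'
#' @param dim embedding size per order (the final separate-mode embedding
#'   has \code{2 * dim} columns).
#' @param negative number of noise nodes contrasted against each positive
#'   draw.
#' @param samples number of edge draws, in units of \code{samplesUnit}.
#' @param samplesUnit \code{"millions"} or \code{"absolute"}.
#' @param alpha joint-mode mixing weight in [0, 1]: each draw performs a
#'   second-order update with probability \code{alpha}, else first-order.
#' @param mode \code{"joint"} (default), \code{"separate"} (train both
#'   orders independently, L2-normalize, concatenate), or a single order
#'   \code{"first"} / \code{"second"}.
#' @param lr initial SGD learning rate; decays linearly to 1/100 of it.
#' @param seed integer seed; training is bit-reproducible given the seed.
#' @param workers accepted for interface compatibility; training runs
#'   single-threaded (deterministic), so values > 1 are rejected.
#' @return a list of class \code{TrainingConfig}.
#' @export
trainingConfig <- function(dim = 100L, negative = 5L, samples = 25,
                           samplesUnit = c("millions", "absolute"),
                           alpha = 0.5,
                           mode = c("joint", "separate", "first", "second"),
                           lr = 0.025, seed = 1L, workers = 1L) {
    samplesUnit <- match.arg(samplesUnit)
    mode <- match.arg(mode)
    if (dim < 1L) stop("dim must be >= 1")
    if (negative < 1L) stop("negative must be >= 1")
    if (samples <= 0) stop("samples must be positive")
    if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
    if (lr <= 0) stop("lr must be positive")
    if (workers != 1L) stop("only single-threaded training is supported")
    structure(list(dim = as.integer(dim), negative = as.integer(negative),
                   samples = samples, samplesUnit = samplesUnit,
                   alpha = alpha, mode = mode, lr = lr,
                   seed = as.integer(seed), workers = 1L),
              class = "TrainingConfig")
}

nDraws <- function(config) {
    round(config$samples * if (config$samplesUnit == "millions") 1e6 else 1)
}

#' First-order proximity probability
#'
#' \eqn{p_1(v_i, v_j) = 1 / (1 + \exp(-u_i \cdot u_j))}: the sigmoid of the
#' dot product of the two vertex vectors, symmetric in its arguments.
#'
#' @param ui,uj numeric vectors of equal length.
#' @return probability in (0, 1).
#' @export
firstOrderProb <- function(ui, uj) {
    if (length(ui) != length(uj)) stop("vector dimensions differ")
    sigmoid(sum(ui * uj))
}

#' Exact first-order objective
#'
#' \eqn{O_1 = -\sum_{(i,j) \in E} w_{ij} \log p_1(v_i, v_j)} by direct
#' summation over the edge list. Used as the training oracle; the SGD loop
#' optimizes a negative-sampling surrogate of this quantity.
#'
#' @param graph a \code{ContactGraph}.
#' @param embedding a \code{NodeEmbedding} (or a matrix with node-id row
#'   names) covering all connected nodes.
#' @return the objective value.
#' @export
firstOrderObjective <- function(graph, embedding) {
    V <- if (is(embedding, "NodeEmbedding")) vertexVectors(embedding)
         else embedding
    ed <- graphEdges(graph)
    ri <- match(as.character(ed$i), rownames(V))
    rj <- match(as.character(ed$j), rownames(V))
    if (any(is.na(ri)) || any(is.na(rj)))
        stop("embedding does not cover all connected nodes")
    dots <- rowSums(V[ri, , drop = FALSE] * V[rj, , drop = FALSE])
    -sum(ed$w * log(sigmoid(dots)))
}

#' Second-order (context) probability
#'
#' \eqn{p_2(v_j | v_i) = \exp(u'_j \cdot u_i) / \sum_{k} \exp(u'_k \cdot
#' u_i)}, the softmax over the candidate context set, computed with
#' max-subtraction for overflow safety. Rows sum to 1 over the context set.
#'
#' @param embedding a \code{NodeEmbedding} with context vectors.
#' @param i source node id (0-based, matching embedding row names).
#' @param j context node id, or a vector of them.
#' @param nodeSet candidate context node ids; defaults to all embedded
#'   nodes.
#' @return probability (vector) in (0, 1).
#' @export
secondOrderProb <- function(embedding, i, j, nodeSet = NULL) {
    V <- vertexVectors(embedding)
    C <- contextVectors(embedding)
    if (!nrow(C)) stop("embedding has no context vectors")
    if (is.null(nodeSet)) nodeSet <- rownames(V)
    nodeSet <- as.character(nodeSet)
    if (!length(nodeSet)) stop("empty context node set")
    ui <- V[as.character(i), ]
    scores <- drop(C[nodeSet, , drop = FALSE] %*% ui)
    scores <- scores - max(scores)
    p <- exp(scores) / sum(exp(scores))
    unname(p[match(as.character(j), nodeSet)])
}

#' Exact second-order objective
#'
#' \eqn{O_2 = -\sum_{(i,j)} w_{ij} \log p_2(v_j | v_i)} with the softmax
#' taken over all embedded nodes and every undirected edge expanded to both
#' directions. Exact summation; feasible only for small graphs and used as
#' the training oracle.
#'
#' @inheritParams firstOrderObjective
#' @export
secondOrderObjective <- function(graph, embedding) {
    V <- vertexVectors(embedding)
    C <- contextVectors(embedding)
    if (!nrow(C)) stop("embedding has no context vectors")
    S <- V %*% t(C)                       # S[a, b] = u'_b . u_a
    m <- apply(S, 1, max)
    lse <- m + log(rowSums(exp(S - m)))   # log-sum-exp per source row
    ed <- graphEdges(graph)
    ri <- match(as.character(ed$i), rownames(V))
    rj <- match(as.character(ed$j), rownames(V))
    if (any(is.na(ri)) || any(is.na(rj)))
        stop("embedding does not cover all connected nodes")
    logp_ij <- S[cbind(ri, rj)] - lse[ri]
    logp_ji <- S[cbind(rj, ri)] - lse[rj]
    -sum(ed$w * (logp_ij + logp_ji))
}

#' One negative-sampling SGD step on the first-order objective
#'
#' Gradient-descent step on \eqn{-\log \sigma(u_i \cdot u_j)} for a
#' positive pair or \eqn{-\log \sigma(-u_i \cdot u_j)} for a sampled
#' noise pair; both vectors move, evaluated at their old values.
#'
#' @param ui,uj vertex vectors.
#' @param label \code{"pos"} or \code{"neg"}.
#' @param lr learning rate (> 0).
#' @return list with updated \code{ui}, \code{uj}.
#' @export
sgdUpdateFirst <- function(ui, uj, label = c("pos", "neg"), lr) {
    label <- match.arg(label)
    if (lr <= 0) stop("lr must be positive")
    if (any(!is.finite(ui)) || any(!is.finite(uj)))
        stop("non-finite vector")
    s <- sigmoid(sum(ui * uj))
    g <- if (label == "pos") (1 - s) else -s
    list(ui = ui + lr * g * uj, uj = uj + lr * g * ui)
}

#' One negative-sampling SGD step on the second-order objective
#'
#' Step on \eqn{-\log \sigma(u'_j \cdot u_i) - \sum_n \log \sigma(-u'_n
#' \cdot u_i)}: the source vertex vector, the positive context and the
#' sampled negative contexts move; nothing else does.
#'
#' @param ui source vertex vector.
#' @param ctxPos positive context vector \eqn{u'_j}.
#' @param ctxNeg matrix of negative context vectors (rows), possibly empty.
#' @param lr learning rate (> 0).
#' @return list with updated \code{ui}, \code{ctxPos}, \code{ctxNeg}.
#' @export
sgdUpdateSecond <- function(ui, ctxPos, ctxNeg = NULL, lr) {
    if (lr <= 0) stop("lr must be positive")
    if (is.null(ctxNeg)) ctxNeg <- matrix(numeric(), 0, length(ui))
    sPos <- sigmoid(sum(ctxPos * ui))
    gradUi <- -(1 - sPos) * ctxPos
    newPos <- ctxPos + lr * (1 - sPos) * ui
    newNeg <- ctxNeg
    if (nrow(ctxNeg)) {
        sNeg <- sigmoid(drop(ctxNeg %*% ui))
        gradUi <- gradUi + drop(sNeg %*% ctxNeg)
        newNeg <- ctxNeg - lr * outer(sNeg, ui)
    }
    list(ui = ui - lr * gradUi, ctxPos = newPos, ctxNeg = newNeg)
}

#' Build the alias samplers for SGD training
#'
#' Edge draws follow \eqn{w_{ij} / W}; negative (noise) node draws follow
#' node strength to the 3/4 power, the standard noise distribution for
#' negative sampling. Both tables give O(1) draws and are reproducible per
#' seed.
#'
#' @param graph a \code{ContactGraph} with at least one edge.
#' @param seed integer seed for subsequent draws.
#' @return an \code{EdgeSampler} list: edge probabilities, node
#'   probabilities, alias tables, and the seed.
#' @export
buildSampler <- function(graph, seed = 1L) {
    ed <- graphEdges(graph)
    if (!nrow(ed)) stop("cannot build a sampler over an empty graph")
    deg <- nodeDegree(graph)
    noise <- deg^0.75
    structure(list(
        edges = ed,
        edgeProb = ed$w / sum(ed$w),
        nodeIds = seq_along(deg) - 1L,
        nodeProb = noise / sum(noise),
        edgeAlias = cpp_build_alias(ed$w),
        nodeAlias = cpp_build_alias(noise),
        seed = as.integer(seed)), class = "EdgeSampler")
}

#' Draw edges / negative nodes from an \code{EdgeSampler}
#'
#' @param sampler an \code{EdgeSampler}.
#' @param n number of draws.
#' @param seed optional override of the sampler's seed.
#' @return \code{sampleEdges}: integer indices into
#'   \code{sampler$edges}; \code{sampleNegatives}: 0-based node ids.
#' @export
sampleEdges <- function(sampler, n, seed = NULL) {
    s <- if (is.null(seed)) sampler$seed else seed
    cpp_alias_draw(sampler$edgeAlias$prob, sampler$edgeAlias$alias, n, s)
}

#' @rdname sampleEdges
#' @export
sampleNegatives <- function(sampler, n, seed = NULL) {
    s <- if (is.null(seed)) sampler$seed else seed
    idx <- cpp_alias_draw(sampler$nodeAlias$prob, sampler$nodeAlias$alias, n, s)
    sampler$nodeIds[idx]
}

#' Train a LINE embedding of the contact graph
#'
#' Runs negative-sampling SGD over weighted edge draws. In joint mode each
#' draw performs a second-order update with probability \code{alpha} and a
#' first-order update otherwise, optimizing \eqn{O_3 = (1-\alpha) O_1 +
#' \alpha O_2} in expectation. In separate mode both orders are trained
#' independently at \code{dim} dimensions each, row-wise L2-normalized and
#' concatenated. Only connected nodes (inter-chromosomal degree > 0) are
#' embedded. The learning rate decays linearly from \code{lr} to
#' \code{lr/100}; vertex vectors start uniform in \eqn{(-0.5/d, 0.5/d)} and
#' context vectors at zero. Deterministic given \code{config$seed}.
#'
#' @param graph a \code{ContactGraph} with at least 2 connected nodes.
#' @param config a \code{\link{trainingConfig}}.
#' @return a \code{NodeEmbedding}; \code{metadata} holds the config, the
#'   initial matrices, and first/second update counters.
#' @export
trainEmbedding <- function(graph, config = trainingConfig()) {
    if (!inherits(config, "TrainingConfig"))
        stop("config must come from trainingConfig()")
    keep <- connectedNodes(graph)
    if (length(keep) < 2L) stop("need at least 2 connected nodes to embed")
    idmap <- match(graphEdges(graph)$i, keep) - 1L   # dense 0-based ids
    jdmap <- match(graphEdges(graph)$j, keep) - 1L
    w <- graphEdges(graph)$w
    nv <- length(keep)
    draws <- nDraws(config)
    rn <- as.character(keep)

    runOrder <- function(order, seed) {
        cpp_line_train(idmap, jdmap, w, nv, config$dim, order, config$alpha,
                       draws, config$negative, config$lr, seed)
    }
    if (config$mode == "separate") {
        f1 <- runOrder(1L, config$seed)
        f2 <- runOrder(2L, config$seed + 1L)
        V <- cbind(l2normalize(f1$vertex), l2normalize(f2$vertex))
        V0 <- cbind(l2normalize(f1$vertex0), l2normalize(f2$vertex0))
        rownames(V) <- rownames(V0) <- rn
        ctx <- f2$context
        rownames(ctx) <- rn
        meta <- list(config = config, vertex0 = V0, context0 = f2$context0,
                     nFirst = f1$nFirst, nSecond = f2$nSecond)
        return(new("NodeEmbedding", vertex = V, context = ctx,
                   mode = "separate", metadata = meta))
    }
    order <- switch(config$mode, first = 1L, second = 2L, joint = 3L)
    fit <- runOrder(order, config$seed)
    V <- fit$vertex
    rownames(V) <- rn
    ctx <- fit$context
    if (nrow(ctx)) rownames(ctx) <- rn
    V0 <- fit$vertex0
    rownames(V0) <- rn
    if (nrow(fit$context0)) rownames(fit$context0) <- rn
    new("NodeEmbedding", vertex = V, context = ctx, mode = config$mode,
        metadata = list(config = config, vertex0 = V0,
                        context0 = fit$context0,
                        nFirst = fit$nFirst, nSecond = fit$nSecond))
}

l2normalize <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- 1
    m / nrm
}

#' Embedding at initialization
#'
#' Reconstructs the \code{NodeEmbedding} as it was before any SGD update,
#' for objective-decrease checks.
#'
#' @param embedding a trained \code{NodeEmbedding}.
#' @return a \code{NodeEmbedding} holding the initial matrices.
#' @export
initialEmbedding <- function(embedding) {
    md <- embedding@metadata
    if (is.null(md$vertex0)) stop("embedding carries no initial state")
    ctx0 <- md$context0
    if (is.null(ctx0) || !nrow(ctx0))
        ctx0 <- matrix(numeric(), 0, ncol(md$vertex0))
    else if (is.null(rownames(ctx0)))
        rownames(ctx0) <- rownames(md$vertex0)
    new("NodeEmbedding", vertex = md$vertex0, context = ctx0,
        mode = embedding@mode, metadata = list())
}
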