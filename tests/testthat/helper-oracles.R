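# Independent brute-force oracles: naive loop implementations of every
# metric, kept deliberately separate from the package's code paths.

oracleSilhouette <- function(points, labels) {
    points <- as.matrix(points)
    n <- nrow(points)
    d <- function(a, b) sqrt(sum((points[a, ] - points[b, ])^2))
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(labels == labels[i] & seq_len(n) != i)
        if (!length(own)) { s[i] <- 0; next }
        a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
        b <- Inf
        for (l in setdiff(unique(labels), labels[i])) {
            oth <- which(labels == l)
            b <- min(b, mean(vapply(oth, function(j) d(i, j), numeric(1))))
        }
        s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    s
}

oracleDBI <- function(points, labels) {
    points <- as.matrix(points)
    d <- function(a, b) sqrt(sum((points[a, ] - points[b, ])^2))
    lv <- sort(unique(labels))
    k <- length(lv)
    wi <- numeric(k)
    for (c in seq_len(k)) {
        ii <- which(labels == lv[c])
        if (length(ii) < 2) next
        tot <- 0; np <- 0
        for (a in seq_along(ii)) for (b in seq_along(ii)) if (a < b) {
            tot <- tot + d(ii[a], ii[b]); np <- np + 1
        }
        wi[c] <- tot / np
    }
    worst <- numeric(k)
    for (a in seq_len(k)) {
        best <- -Inf
        for (b in seq_len(k)) {
            if (a == b) next
            ia <- which(labels == lv[a]); ib <- which(labels == lv[b])
            tot <- 0
            for (x in ia) for (y in ib) tot <- tot + d(x, y)
            dij <- tot / (length(ia) * length(ib))
            best <- max(best, (wi[a] + wi[b]) / dij)
        }
        worst[a] <- best
    }
    mean(worst)
}

# All-pairs shortest paths with path counts (Floyd-Warshall), tolerance-
# aware for weighted graphs. edges: data.frame(i, j, w) over 0-based ids
# 0..(n-1); mode "hop" or "invweight".
oracleAPSP <- function(edges, n, mode = "hop", tol = 1e-12) {
    W <- matrix(Inf, n, n)
    for (r in seq_len(nrow(edges))) {
        a <- edges$i[r] + 1L; b <- edges$j[r] + 1L
        len <- if (mode == "hop") 1 else 1 / edges$w[r]
        W[a, b] <- W[b, a] <- min(W[a, b], len)
    }
    D <- W; diag(D) <- 0
    for (k in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n)) {
        alt <- D[a, k] + D[k, b]
        if (alt < D[a, b]) D[a, b] <- alt
    }
    # path counts by DP in order of distance from each source
    S <- matrix(0, n, n); diag(S) <- 1
    for (s in seq_len(n)) {
        ord <- order(D[s, ])
        for (v in ord) {
            if (v == s || !is.finite(D[s, v])) next
            cnt <- 0
            for (u in seq_len(n))
                if (is.finite(W[u, v]) &&
                    abs(D[s, u] + W[u, v] - D[s, v]) <= tol)
                    cnt <- cnt + S[s, u]
            S[s, v] <- cnt
        }
    }
    list(D = D, S = S)
}

oracleCloseness <- function(edges, n, mode = "hop") {
    ap <- oracleAPSP(edges, n, mode)
    vapply(seq_len(n), function(u) {
        reach <- which(is.finite(ap$D[, u]) & seq_len(n) != u)
        nu <- length(reach) + 1L
        if (nu < 2) return(0)
        ((nu - 1) / (n - 1)) * ((nu - 1) / sum(ap$D[reach, u]))
    }, numeric(1))
}

oracleBetweenness <- function(edges, n, mode = "hop", tol = 1e-12) {
    ap <- oracleAPSP(edges, n, mode)
    out <- numeric(n)
    for (u in seq_len(n)) {
        tot <- 0
        for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
            if (s == u || t == u || !is.finite(ap$D[s, t])) next
            through <- if (is.finite(ap$D[s, u]) && is.finite(ap$D[u, t]) &&
                           abs(ap$D[s, u] + ap$D[u, t] - ap$D[s, t]) <= tol)
                ap$S[s, u] * ap$S[u, t] else 0
            tot <- tot + through / ap$S[s, t]
        }
        out[u] <- tot
    }
    out
}

oracleBarrat <- function(edges, n) {
    W <- matrix(0, n, n)
    for (r in seq_len(nrow(edges))) {
        a <- edges$i[r] + 1L; b <- edges$j[r] + 1L
        W[a, b] <- W[b, a] <- edges$w[r]
    }
    vapply(seq_len(n), function(u) {
        nb <- which(W[u, ] > 0)
        k <- length(nb)
        if (k < 2) return(0)
        s <- sum(W[u, nb])
        tot <- 0
        # ordered neighbor pairs, as in Barrat's definition: reduces to the
        # plain closed-triplet ratio on unit weights
        for (a in seq_along(nb)) for (b in seq_along(nb)) if (a != b) {
            v <- nb[a]; w <- nb[b]
            if (W[v, w] > 0) tot <- tot + (W[u, v] + W[u, w]) / 2
        }
        tot / (s * (k - 1))
    }, numeric(1))
}

# Exhaustive two-sided Fisher p: sum of hypergeometric probabilities of
# all tables with the observed margins that are no more probable.
oracleFisherP <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- vapply(lo:hi, function(x) dhyper(x, m, n, k), numeric(1))
    pObs <- dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exact second-order softmax evaluated directly from the matrices
oracleSoftmaxProb <- function(V, C, i, j) {
    num <- exp(sum(C[j, ] * V[i, ]))
    den <- sum(exp(C %*% V[i, ]))
    num / den
}
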