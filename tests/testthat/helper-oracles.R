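# Independent brute-force oracles used to validate the geometry and
# statistics implementations on small instances.

# Delaunay edges by exhaustive empty-circumcircle/circumsphere search:
# in general position, (i, j) share a Delaunay edge iff some circumsphere
# through i, j and D-1 further points contains no other point.
oracleDelaunayEdges <- function(coords) {
    n <- nrow(coords)
    D <- ncol(coords)
    adj <- matrix(FALSE, n, n)
    combs <- utils::combn(n, D + 1L)
    for (c in seq_len(ncol(combs))) {
        idx <- combs[, c]
        P <- coords[idx, , drop = FALSE]
        A <- 2 * sweep(P[-1, , drop = FALSE], 2, P[1, ], "-")
        b <- rowSums(P[-1, , drop = FALSE]^2) - sum(P[1, ]^2)
        ctr <- tryCatch(solve(A, b), error = function(e) NULL)
        if (is.null(ctr)) next
        r2 <- sum((P[1, ] - ctr)^2)
        d2 <- rowSums(sweep(coords, 2, ctr, "-")^2)
        if (any(d2[-idx] < r2 * (1 - 1e-9))) next
        for (a in seq_along(idx))
            for (b2 in seq_along(idx))
                if (a < b2) adj[idx[a], idx[b2]] <- TRUE
    }
    adj | t(adj)
}

# all-pairs mutual k-nearest-neighbor pairing between two point sets
oracleMutualKnn <- function(ca, cb, k) {
    da <- as.matrix(dist(rbind(ca, cb)))[seq_len(nrow(ca)),
                                         nrow(ca) + seq_len(nrow(cb)),
                                         drop = FALSE]
    rA <- t(apply(da, 1, rank, ties.method = "first"))  # rank of B within A's row
    rB <- apply(da, 2, rank, ties.method = "first")     # rank of A within B's col
    (rA <= min(k, ncol(da))) & (rB <= min(k, nrow(da)))
}

# conditional-permutation LISA reference for one cell
oracleLisaConditional <- function(x, W, i, nPerm) {
    n <- length(x)
    z <- x - mean(x)
    ss <- sum(z^2)
    nb <- which(W[i, ] > 0)
    obs <- (n / ss) * z[i] * sum(z[nb])
    others <- z[-i]
    st <- replicate(nPerm, (n / ss) * z[i] * sum(sample(others, length(nb))))
    list(obs = obs, stats = st,
         p = (1 + sum(st >= obs)) / (1 + nPerm))
}

randomCells <- function(n, d = 2, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    m <- matrix(runif(n * d), n, d)
    rownames(m) <- sprintf("c%d", seq_len(n))
    m
}
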