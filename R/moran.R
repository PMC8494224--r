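# Global spatial autocorrelation: Moran's I with analytic null moments under
# the randomization (permutation) assumption, so per-gene significance needs
# no Monte Carlo. For N cells with binary symmetric weights W,
#   I = N / Wsum * sum_ij W_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
# with Wsum = sum_ij W_ij. Under random permutation of x over positions,
#   E(I)   = -1 / (N - 1)
#   Var(I) = (N*S4 - S3*S5) / ((N-1)(N-2)(N-3) Wsum^2) - E(I)^2
# where S1 = 1/2 sum_ij (W_ij + W_ji)^2, S2 = sum_i (W_i. + W_.i)^2,
# S3 is the sample kurtosis of x, S4 = (N^2-3N+3)S1 - N*S2 + 3 Wsum^2 and
# S5 = (N^2-N)S1 - 2N*S2 + 6 Wsum^2 (the classical Cliff-Ord moments; the
# permutation oracle in the test suite confirms this form).

# align a per-cell vector to the weights' cell ids
.alignVec <- function(x, weights, what = "x") {
    ids <- cellIds(weights)
    if (!is.null(names(x))) {
        if (!all(ids %in% names(x)))
            stop(what, " is missing values for some cells in weights")
        x <- x[ids]
    } else if (length(x) != length(ids)) {
        stop(what, " must have one value per cell (", length(ids), ")")
    }
    x <- as.numeric(x)
    if (any(!is.finite(x))) stop("non-finite values in ", what)
    x
}

.alignMat <- function(x, weights) {
    ids <- cellIds(weights)
    x <- as.matrix(x)
    if (!is.null(colnames(x))) {
        if (!all(ids %in% colnames(x)))
            stop("expression matrix is missing cells present in weights")
        x <- x[, ids, drop = FALSE]
    } else if (ncol(x) != length(ids)) {
        stop("expression matrix must have one column per cell")
    }
    if (is.null(rownames(x))) rownames(x) <- sprintf("gene%d", seq_len(nrow(x)))
    x
}

.checkGraph <- function(weights) {
    if (totalWeight(weights) <= 0)
        stop("adjacency matrix has no edges; nothing to analyze")
}

# graph-only constants entering Var(I)
.moranGraphConst <- function(weights) {
    W <- weights@W
    n <- nrow(W)
    wsum <- sum(W)
    nE <- wsum / 2
    deg <- Matrix::rowSums(W)
    S1 <- 4 * nE                 # binary symmetric: (W_ij + W_ji)^2 = 4 per edge
    S2 <- 4 * sum(deg^2)
    list(n = n, wsum = wsum, S1 = S1, S2 = S2,
         S4 = (n^2 - 3 * n + 3) * S1 - n * S2 + 3 * wsum^2,
         S5 = (n^2 - n) * S1 - 2 * n * S2 + 6 * wsum^2)
}

#' Moran's I for one gene
#'
#' @param x per-cell expression values (named by cell id or aligned to
#'   \code{cellIds(weights)}); must be non-constant.
#' @param weights a \code{\link{SpatialWeights}}.
#' @return the Moran's I statistic (a single number). Values near +1
#'   indicate spatial aggregation of similar magnitudes, values near
#'   \eqn{-1} alternation, and values near \eqn{E(I) = -1/(N-1)} no spatial
#'   structure.
#' @examples
#' pos <- simulatePositions(100, seed = 1)
#' sw <- delaunayAdjacency(pos)
#' sim <- simulatePatternGenes(pos, "two_blob", nGenes = 1, seed = 1)
#' moransI(sim$expr[1, ], sw)
#' @export
moransI <- function(x, weights) {
    .checkGraph(weights)
    z <- .alignVec(x, weights)
    if (max(z) == min(z))
        stop("Moran's I is not defined for constant signals")
    zc <- z - mean(z)
    e <- edgeList(weights)
    n <- length(z)
    (n / totalWeight(weights)) *
        (2 * sum(zc[e[, 1]] * zc[e[, 2]])) / sum(zc^2)
}

#' Analytic null moments of Moran's I
#'
#' Expectation and variance of I under the randomization null (all
#' permutations of \code{x} over the fixed positions equally likely).
#'
#' @inheritParams moransI
#' @return named numeric vector \code{c(expected, variance)}.
#' @export
moranMoments <- function(x, weights) {
    .checkGraph(weights)
    z <- .alignVec(x, weights)
    n <- length(z)
    if (n <= 3) stop("null variance requires N > 3 cells")
    if (max(z) == min(z))
        stop("Moran's I is not defined for constant signals")
    zc <- z - mean(z)
    ss <- sum(zc^2)
    S3 <- n * sum(zc^4) / ss^2
    g <- .moranGraphConst(weights)
    ex <- -1 / (n - 1)
    v <- (g$n * g$S4 - S3 * g$S5) /
        ((n - 1) * (n - 2) * (n - 3) * g$wsum^2) - ex^2
    c(expected = ex, variance = v)
}

.moranTestCore <- function(x, weights,
                           alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    .checkGraph(weights)
    X <- .alignMat(x, weights)
    n <- ncol(X)
    if (n <= 3) stop("null variance requires N > 3 cells")
    const <- apply(X, 1L, function(r) max(r) == min(r))
    if (any(const)) {
        message("omitting ", sum(const),
                " gene(s) without expression variability")
        X <- X[!const, , drop = FALSE]
    }
    if (!nrow(X)) stop("no non-constant genes to test")
    g <- .moranGraphConst(weights)
    e <- edgeList(weights)
    Z <- X - rowMeans(X)
    ss <- rowSums(Z^2)
    num <- 2 * rowSums(Z[, e[, 1], drop = FALSE] * Z[, e[, 2], drop = FALSE])
    I <- (n / g$wsum) * num / ss
    S3 <- n * rowSums(Z^4) / ss^2
    ex <- -1 / (n - 1)
    v <- (g$n * g$S4 - S3 * g$S5) /
        ((n - 1) * (n - 2) * (n - 3) * g$wsum^2) - ex^2
    zstat <- (I - ex) / sqrt(v)
    p <- if (alternative == "greater") pnorm(zstat, lower.tail = FALSE)
         else 2 * pnorm(abs(zstat), lower.tail = FALSE)
    S4Vectors::DataFrame(
        observed = I, expected = ex, variance = v, z = zstat,
        p.value = p, p.adj = p.adjust(p, method = "BH"),
        row.names = rownames(X))
}

#' Test genes for significant positive spatial autocorrelation
#'
#' Computes Moran's I, its analytic null moments, a z score, a one-sided
#' (upper-tail, positive autocorrelation) normal p-value and BH-adjusted
#' p-values for every non-constant gene. A two-sided alternative is
#' available via \code{alternative = "two.sided"}.
#'
#' @param x a genes x cells matrix, a per-cell numeric vector, or a
#'   \code{\link{SpatialExpressionSet}}.
#' @param weights a \code{\link{SpatialWeights}} aligned to the cells.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @param ... passed between methods.
#' @return a \code{DataFrame} with columns \code{observed}, \code{expected},
#'   \code{variance}, \code{z}, \code{p.value}, \code{p.adj}; rownames are
#'   gene ids.
#' @examples
#' pos <- simulatePositions(120, seed = 1)
#' sw <- delaunayAdjacency(pos)
#' sim <- simulatePatternGenes(pos, "gradient", nGenes = 3, seed = 2)
#' moranTest(sim$expr, sw)
#' @export
setMethod("moranTest", signature(x = "matrix", weights = "SpatialWeights"),
    function(x, weights, alternative = c("greater", "two.sided"), ...)
        .moranTestCore(x, weights, alternative))

#' @rdname moranTest-matrix-SpatialWeights-method
#' @export
setMethod("moranTest", signature(x = "numeric", weights = "SpatialWeights"),
    function(x, weights, alternative = c("greater", "two.sided"), ...)
        .moranTestCore(matrix(x, 1L, dimnames = list("x", names(x))),
                       weights, alternative))

#' @rdname moranTest-matrix-SpatialWeights-method
#' @export
setMethod("moranTest",
    signature(x = "SpatialExpressionSet", weights = "SpatialWeights"),
    function(x, weights, alternative = c("greater", "two.sided"), ...)
        .moranTestCore(as.matrix(SummarizedExperiment::assay(x)),
                       weights, alternative))

# permuted Moran's I statistics, vectorized over shuffles
.moranPermStats <- function(zc, e, wsum, nPerm, blockSize = 2000L) {
    n <- length(zc)
    denom <- sum(zc^2)
    ei <- e[, 1]; ej <- e[, 2]
    out <- numeric(nPerm)
    done <- 0L
    while (done < nPerm) {
        b <- min(blockSize, nPerm - done)
        idx <- vapply(seq_len(b), function(k) sample.int(n), integer(n))
        Zp <- matrix(zc[idx], n, b)
        num <- 2 * colSums(Zp[ei, , drop = FALSE] * Zp[ej, , drop = FALSE])
        out[done + seq_len(b)] <- (n / wsum) * num / denom
        done <- done + b
    }
    out
}

#' Permutation test for Moran's I
#'
#' Monte Carlo reference for the closed-form test: shuffles expression
#' values over the fixed positions and compares the observed I with the
#' permutation distribution. Intended for validating the analytic moments
#' or for data whose generating mechanism violates the randomization null.
#'
#' @inheritParams moransI
#' @param nPerm number of random permutations.
#' @param seed integer seed (results are reproducible given the seed).
#' @param returnStats logical; also return the permuted statistics.
#' @return list with \code{observed}, one-sided upper-tail \code{p.value}
#'   computed with the (r+1)/(n+1) convention, \code{permMean},
#'   \code{permVar}, \code{nPerm}, and optionally \code{stats}.
#' @export
moranPermutationTest <- function(x, weights, nPerm = 1000L, seed = 0L,
                                 returnStats = FALSE) {
    obs <- moransI(x, weights)
    z <- .alignVec(x, weights)
    zc <- z - mean(z)
    set.seed(seed)
    st <- .moranPermStats(zc, edgeList(weights), totalWeight(weights), nPerm)
    res <- list(observed = obs,
                p.value = (1 + sum(st >= obs)) / (1 + nPerm),
                permMean = mean(st), permVar = var(st), nPerm = nPerm)
    if (returnStats) res$stats <- st
    res
}
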