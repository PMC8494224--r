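# Cell-cell communication inference. For a receptor expressed by cell type A
# and a ligand by cell type B, spatially complementary expression across the
# A-B interface shows up as a positive inter-cell-type spatial
# cross-correlation:
#   iSCI = (N + M) / (2 sum W_ict) * sum_i sum_j W_ict_ij (x_i - xbar)(y_j - ybar)
#          / sqrt(sum_A (x_i - xbar)^2 * sum_B (y_j - ybar)^2)
# with x over the N type-A cells, y over the M type-B cells and means taken
# within type. Significance comes from a random-label permutation null that
# holds positions and W_ict fixed and shuffles x across A cells and y across
# B cells, with an adaptive escalation ladder (100 -> 1000 -> ... shuffles)
# so that only promising pairs pay for precise p-values.

.itwEdges <- function(itw) {
    e <- Matrix::which(itw@W != 0, arr.ind = TRUE)
    dimnames(e) <- list(NULL, c("a", "b"))
    e
}

.alignSide <- function(x, ids, what) {
    if (!is.null(names(x))) {
        if (!all(ids %in% names(x)))
            stop(what, " is missing values for some cells")
        x <- x[ids]
    } else if (length(x) != length(ids)) {
        stop(what, " must have one value per cell (", length(ids), ")")
    }
    as.numeric(x)
}

#' Inter-cell-type spatial cross-correlation (iSCI)
#'
#' @param x expression of a gene over the type-A cells (rows of
#'   \code{weights}), named by cell id or aligned.
#' @param y expression of a gene over the type-B cells (columns).
#' @param weights an \code{\link{InterTypeWeights}} with at least one
#'   inter-type edge.
#' @return a single number; positive values indicate spatially
#'   complementary expression across the type interface.
#' @export
interTypeCrossCor <- function(x, y, weights) {
    stopifnot(methods::is(weights, "InterTypeWeights"))
    wsum <- sum(weights@W)
    if (wsum == 0) stop("no inter-type edges; iSCI is undefined")
    zx <- .alignSide(x, rownames(weights@W), "x")
    zy <- .alignSide(y, colnames(weights@W), "y")
    if (max(zx) == min(zx) || max(zy) == min(zy))
        stop("iSCI is not defined for constant signals")
    zx <- zx - mean(zx); zy <- zy - mean(zy)
    e <- .itwEdges(weights)
    ((length(zx) + length(zy)) / (2 * wsum)) *
        sum(zx[e[, 1]] * zy[e[, 2]]) / sqrt(sum(zx^2) * sum(zy^2))
}

# permuted iSCI statistics, vectorized over shuffles
.isciPermStats <- function(zx, zy, e, wsum, nPerm, blockSize = 2000L) {
    nA <- length(zx); nB <- length(zy)
    denom <- sqrt(sum(zx^2) * sum(zy^2))
    fac <- (nA + nB) / (2 * wsum)
    out <- numeric(nPerm)
    done <- 0L
    while (done < nPerm) {
        b <- min(blockSize, nPerm - done)
        ia <- vapply(seq_len(b), function(k) sample.int(nA), integer(nA))
        ib <- vapply(seq_len(b), function(k) sample.int(nB), integer(nB))
        Xa <- matrix(zx[ia], nA, b)[e[, 1], , drop = FALSE]
        Yb <- matrix(zy[ib], nB, b)[e[, 2], , drop = FALSE]
        out[done + seq_len(b)] <- fac * colSums(Xa * Yb) / denom
        done <- done + b
    }
    out
}

#' Adaptive permutation p-value
#'
#' One-sided upper-tail Monte Carlo p-value with the (r+1)/(n+1)
#' convention (never exactly zero, as BH requires). Testing starts at
#' \code{basePerms} shuffles; whenever no permuted statistic reaches the
#' observed one (estimate below 1/n), the budget escalates by
#' \code{ladderFactor} with a fresh derived seed, up to \code{maxPerms}.
#' Results are reproducible given \code{seed} and do not depend on any
#' parallel worker count (the draws are a pure function of the seed).
#'
#' @param observed the observed statistic.
#' @param permFun function(nPerm, seed) returning \code{nPerm} permuted
#'   statistics.
#' @param basePerms initial number of shuffles (>= 20; default 100).
#' @param ladderFactor escalation multiplier (default 10).
#' @param maxPerms escalation cap (default 10000).
#' @param seed integer seed.
#' @return list with \code{p.value} and \code{nPerm} (permutations used).
#' @export
adaptivePermutationTest <- function(observed, permFun, basePerms = 100L,
                                    ladderFactor = 10L, maxPerms = 10000L,
                                    seed = 0L) {
    if (basePerms < 20L) stop("basePerms must be >= 20 (p would be too coarse)")
    if (ladderFactor < 2L) stop("ladderFactor must be >= 2")
    n <- as.integer(basePerms)
    level <- 0L
    repeat {
        st <- permFun(n, seed + level)
        p <- (1 + sum(st >= observed)) / (1 + n)
        if (p >= 1 / n || n >= maxPerms) break
        n <- as.integer(min(n * ladderFactor, maxPerms))
        level <- level + 1L
    }
    list(p.value = p, nPerm = n)
}

#' Screen receptor-ligand pairs for spatial cross-correlation
#'
#' For every receptor-ligand pair whose two genes are well detected in
#' their respective cell populations, computes the iSCI across the
#' type-A/type-B interface and an adaptive random-label permutation
#' p-value, then BH-adjusts across all tested pairs in the screen.
#' Direction matters: \code{"AB"} places the receptor in \code{typeA} cells
#' and the ligand in \code{typeB} cells; \code{"BA"} the reverse. The two
#' screens are reported separately by design.
#'
#' @param x genes x cells expression matrix (normalized), or a
#'   \code{\link{SpatialExpressionSet}}.
#' @param types per-cell type labels (named by cell id or aligned to
#'   \code{weights}).
#' @param weights a \code{\link{SpatialWeights}} over all cells.
#' @param pairs data.frame with columns \code{receptor} and \code{ligand}
#'   (gene ids); duplicate pairs are rejected.
#' @param typeA,typeB cell-type labels.
#' @param direction \code{"AB"} (receptor in A; default) or \code{"BA"}.
#' @param minCells detection threshold: each gene must be nonzero in
#'   strictly more than \code{minCells} cells of its population (default 30).
#' @param basePerms,ladderFactor,maxPerms adaptive permutation ladder; see
#'   \code{\link{adaptivePermutationTest}}.
#' @param seed integer seed; pair k uses the derived seed
#'   \code{seed + 1000 * k} so results do not depend on evaluation order.
#' @return a \code{DataFrame} with one row per tested pair: receptor,
#'   ligand, typeA, typeB, direction, isci, n_edges, n_perm, p.value,
#'   p.adj. Empty (with a warning) when no pair survives filtering.
#' @examples
#' sim <- simulateCommunication(simulatePositions(300, seed = 1),
#'                              nPairs = 3, seed = 1)
#' sw <- delaunayAdjacency(simulatePositions(300, seed = 1))
#' screenPairs(sim$expr, sim$types, sw, sim$pairs, "A", "B",
#'             minCells = 10, seed = 1)
#' @export
screenPairs <- function(x, types, weights, pairs, typeA, typeB,
                        direction = c("AB", "BA"), minCells = 30L,
                        basePerms = 100L, ladderFactor = 10L,
                        maxPerms = 10000L, seed = 0L) {
    direction <- match.arg(direction)
    if (methods::is(x, "SpatialExpressionSet"))
        x <- as.matrix(SummarizedExperiment::assay(x))
    X <- .alignMat(x, weights)
    pairs <- as.data.frame(pairs)
    if (!all(c("receptor", "ligand") %in% colnames(pairs)))
        stop("pairs must have columns 'receptor' and 'ligand'")
    if (anyDuplicated(pairs[, c("receptor", "ligand")]))
        stop("duplicate receptor-ligand pairs")
    itw <- interTypeAdjacency(weights, types, typeA, typeB)
    if (sum(itw@W) == 0)
        stop("no inter-type edges between '", typeA, "' and '", typeB, "'")
    aIds <- rownames(itw@W); bIds <- colnames(itw@W)
    e <- .itwEdges(itw)
    wsum <- sum(itw@W)
    # receptor lives in A for "AB", in B for "BA"
    recIds <- if (direction == "AB") aIds else bIds
    ligIds <- if (direction == "AB") bIds else aIds
    known <- pairs$receptor %in% rownames(X) & pairs$ligand %in% rownames(X)
    detRec <- detectionFilter(X[, recIds, drop = FALSE], minCells)
    detLig <- detectionFilter(X[, ligIds, drop = FALSE], minCells)
    keep <- known & pairs$receptor %in% detRec & pairs$ligand %in% detLig
    if (!any(keep)) {
        warning("no receptor-ligand pair survives the detection filter")
        return(S4Vectors::DataFrame(
            receptor = character(0), ligand = character(0),
            typeA = character(0), typeB = character(0),
            direction = character(0), isci = numeric(0),
            n_edges = integer(0), n_perm = integer(0),
            p.value = numeric(0), p.adj = numeric(0)))
    }
    tested <- pairs[keep, , drop = FALSE]
    res <- lapply(seq_len(nrow(tested)), function(k) {
        rec <- tested$receptor[k]; lig <- tested$ligand[k]
        xa <- if (direction == "AB") X[rec, aIds] else X[lig, aIds]
        yb <- if (direction == "AB") X[lig, bIds] else X[rec, bIds]
        if (max(xa) == min(xa) || max(yb) == min(yb))
            return(list(isci = NA_real_, p = NA_real_, n = NA_integer_))
        obs <- interTypeCrossCor(xa, yb, itw)
        zx <- xa - mean(xa); zy <- yb - mean(yb)
        ad <- adaptivePermutationTest(
            obs,
            function(nPerm, s) {
                set.seed(s)
                .isciPermStats(zx, zy, e, wsum, nPerm)
            },
            basePerms = basePerms, ladderFactor = ladderFactor,
            maxPerms = maxPerms, seed = seed + 1000L * k)
        list(isci = obs, p = ad$p.value, n = ad$nPerm)
    })
    p <- vapply(res, `[[`, numeric(1), "p")
    out <- S4Vectors::DataFrame(
        receptor = tested$receptor, ligand = tested$ligand,
        typeA = typeA, typeB = typeB, direction = direction,
        isci = vapply(res, `[[`, numeric(1), "isci"),
        n_edges = as.integer(wsum),
        n_perm = vapply(res, `[[`, integer(1), "n"),
        p.value = p, p.adj = p.adjust(p, method = "BH"))
    out[order(out$p.value), ]
}
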