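# Spatial cross-correlation between genes and grouping into primary spatial
# patterns. The spatial cross-correlation index between genes x and y is
#   SCI = N / (2 Wsum) * sum_ij W_ij (x_i - xbar)(y_j - ybar)
#         / sqrt(sum_i (x_i - xbar)^2 * sum_j (y_j - ybar)^2)
# Under this normalization sci(x, x) = moransI(x)/2; only relative values
# matter downstream (the matrix feeds a clustering), so the global factor is
# immaterial.

#' Spatial cross-correlation index between two genes
#'
#' Positive when high values of \code{x} sit next to high values of
#' \code{y}; generalizes Moran's I to gene pairs
#' (\code{spatialCrossCor(x, x, w) == moransI(x, w) / 2}).
#'
#' @param x,y per-cell expression vectors, non-constant, aligned to
#'   \code{weights}.
#' @param weights a \code{\link{SpatialWeights}}.
#' @return a single number.
#' @export
spatialCrossCor <- function(x, y, weights) {
    .checkGraph(weights)
    zx <- .alignVec(x, weights, "x")
    zy <- .alignVec(y, weights, "y")
    if (max(zx) == min(zx) || max(zy) == min(zy))
        stop("spatial cross-correlation is not defined for constant signals")
    zx <- zx - mean(zx); zy <- zy - mean(zy)
    e <- edgeList(weights)
    n <- length(zx)
    num <- sum(zx[e[, 1]] * zy[e[, 2]]) + sum(zx[e[, 2]] * zy[e[, 1]])
    (n / (2 * totalWeight(weights))) * num /
        sqrt(sum(zx^2) * sum(zy^2))
}

#' All-pairs spatial cross-correlation matrix
#'
#' Computes the symmetric G x G matrix of pairwise spatial
#' cross-correlations via a single sparse product; entries are identical to
#' looping \code{\link{spatialCrossCor}} over pairs.
#'
#' @param x genes x cells matrix of (at least two) selected genes.
#' @param weights a \code{\link{SpatialWeights}}.
#' @return a symmetric numeric matrix with gene ids as dimnames; the
#'   diagonal equals each gene's Moran's I divided by 2.
#' @examples
#' pos <- simulatePositions(100, seed = 1)
#' sw <- delaunayAdjacency(pos)
#' sim <- simulatePatternGenes(pos, "stripes", nGenes = 4, seed = 1)
#' spatialCrossCorMatrix(sim$expr, sw)
#' @export
spatialCrossCorMatrix <- function(x, weights) {
    .checkGraph(weights)
    X <- .alignMat(x, weights)
    if (nrow(X) < 2) stop("need at least two genes")
    const <- apply(X, 1L, function(r) max(r) == min(r))
    if (any(const)) stop("constant gene(s): ",
                         paste(rownames(X)[const], collapse = ", "))
    n <- ncol(X)
    Z <- X - rowMeans(X)
    ss <- rowSums(Z^2)
    A <- as.matrix(Z %*% weights@W %*% t(Z))   # A_gh = sum_ij W_ij z_gi z_hj
    sci <- (n / (2 * totalWeight(weights))) * A / sqrt(outer(ss, ss))
    dimnames(sci) <- list(rownames(X), rownames(X))
    sci
}

#' Group spatially heterogeneous genes into primary patterns
#'
#' Hierarchically clusters genes on the dissimilarity
#' \code{max(sci) - sci} with average linkage and cuts the dendrogram
#' adaptively: candidate flat cuts (2 .. \code{kMax} groups) are scored by
#' mean silhouette width on the same dissimilarity and the best cut is
#' kept; groups smaller than \code{minPatternSize} are reassigned to
#' pattern 0 ("unassigned"). The procedure is deterministic and invariant
#' to gene input order.
#'
#' @param sci a spatial cross-correlation matrix from
#'   \code{\link{spatialCrossCorMatrix}}.
#' @param minPatternSize smallest admissible pattern (default 5 genes).
#' @param kMax largest number of candidate patterns examined (default 10).
#' @return list with \code{pattern} (named integer vector; 0 = unassigned),
#'   \code{k} (number of patterns), and \code{hclust} (the dendrogram).
#' @export
groupPatterns <- function(sci, minPatternSize = 5L, kMax = 10L) {
    g <- nrow(sci)
    if (is.null(rownames(sci))) stop("sci must carry gene ids")
    if (g < minPatternSize) {
        warning("fewer genes (", g, ") than minPatternSize (",
                minPatternSize, "); returning a single pattern")
        return(list(pattern = setNames(rep(1L, g), rownames(sci)), k = 1L,
                    hclust = NULL))
    }
    d <- max(sci) - sci
    diag(d) <- 0
    hc <- hclust(as.dist(d), method = "average")
    ks <- 2:min(kMax, g - 1L)
    silw <- vapply(ks, function(k) {
        cl <- cutree(hc, k = k)
        mean(cluster::silhouette(cl, dmatrix = d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(silw)]
    cl <- cutree(hc, k = k)
    sizes <- table(cl)
    small <- as.integer(names(sizes)[sizes < minPatternSize])
    cl[cl %in% small] <- 0L
    # renumber surviving patterns 1..k' by order of first appearance in the
    # dendrogram ordering, so labels do not depend on input order
    keep <- unique(cl[hc$order][cl[hc$order] != 0L])
    map <- setNames(seq_along(keep), keep)
    out <- ifelse(cl == 0L, 0L, map[as.character(cl)])
    list(pattern = setNames(as.integer(out), rownames(sci)),
         k = length(keep), hclust = hc)
}

#' Summarize spatial patterns across cells
#'
#' Each member gene is Z-scored across cells (mean 0, sd 1) and the scores
#' averaged per pattern, yielding one summary value per cell per pattern.
#'
#' @param x genes x cells matrix covering all assigned genes.
#' @param patterns result of \code{\link{groupPatterns}} or a named pattern
#'   id vector (0 entries are skipped).
#' @return cells x patterns numeric matrix (columns \code{pattern1}, ...).
#' @export
summarizePatterns <- function(x, patterns) {
    if (is.list(patterns)) patterns <- patterns$pattern
    x <- as.matrix(x)
    pat <- sort(unique(patterns[patterns != 0L]))
    if (!length(pat)) stop("no assigned patterns to summarize")
    genes <- names(patterns)
    if (!all(genes %in% rownames(x)))
        stop("pattern genes missing from expression matrix")
    out <- vapply(pat, function(p) {
        member <- genes[patterns == p]
        zm <- x[member, , drop = FALSE]
        sds <- apply(zm, 1L, sd)
        if (any(sds == 0)) stop("cannot Z-score constant gene in pattern ", p)
        colMeans((zm - rowMeans(zm)) / sds)
    }, numeric(ncol(x)))
    dimnames(out) <- list(colnames(x), sprintf("pattern%d", pat))
    out
}

#' Interpolate a per-cell field onto a regular grid
#'
#' Smooth scattered-data interpolation of a pattern summary (or any
#' per-cell value) onto a \code{resolution} x \code{resolution} grid over
#' the bounding box, for display. Grid nodes outside the convex hull of the
#' positions are NA. 2D positions only; interpolate multilayer data one
#' section at a time.
#'
#' @param x 2D positions (matrix or data.frame).
#' @param values per-cell numeric values.
#' @param resolution grid resolution per axis (>= 2, default 100).
#' @param method \code{interp} method; the default bilinear interpolant
#'   reproduces cell values exactly at their own locations.
#' @return list with \code{x}, \code{y} grid coordinates and the
#'   \code{resolution}-square matrix \code{z}.
#' @export
interpolatePattern <- function(x, values, resolution = 100L,
                               method = "linear") {
    coords <- .asCoords(x)
    if (ncol(coords) != 2L)
        stop("grid interpolation is 2D only; interpolate per section for 3D")
    if (resolution < 2L) stop("resolution must be >= 2")
    if (length(values) != nrow(coords))
        stop("one value per cell required")
    interp::interp(coords[, 1], coords[, 2], values,
                   xo = seq(min(coords[, 1]), max(coords[, 1]),
                            length.out = resolution),
                   yo = seq(min(coords[, 2]), max(coords[, 2]),
                            length.out = resolution),
                   method = method)
}
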