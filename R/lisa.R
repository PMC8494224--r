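# Local indicators of spatial association (LISA). Each cell's contribution
# to the global statistic is
#   I_i = N (x_i - xbar) sum_j W_ij (x_j - xbar) / sum_i (x_i - xbar)^2
# which satisfies the identity sum_i I_i = Wsum * I for binary weights.
# Per-cell significance uses the conditional-randomization moments
# (Anselin 1995): holding x_i fixed, the remaining values are a random
# permutation over the other N-1 positions, so sum_j W_ij x_j is a sum of
# deg_i draws without replacement from the leave-one-out population, giving
# exact first and second moments for I_i. The fraction of cells whose LISA
# is individually significant ("driving fraction") measures the scale of a
# gene's spatial pattern and guards against tiny-hotspot artifacts.

#' Local spatial association scores
#'
#' @inheritParams moransI
#' @return per-cell LISA values \eqn{I_i}; \code{sum(lisaScores(x, w))}
#'   equals \code{totalWeight(w) * moransI(x, w)}.
#' @examples
#' pos <- simulatePositions(80, seed = 1)
#' sw <- delaunayAdjacency(pos)
#' sim <- simulatePatternGenes(pos, "hotspot", nGenes = 1, seed = 1)
#' head(lisaScores(sim$expr[1, ], sw))
#' @export
lisaScores <- function(x, weights) {
    .checkGraph(weights)
    z <- .alignVec(x, weights)
    if (max(z) == min(z))
        stop("LISA is not defined for constant signals")
    zc <- z - mean(z)
    s <- as.vector(weights@W %*% zc)
    setNames(length(z) * zc * s / sum(zc^2), cellIds(weights))
}

#' Signed local spatial association
#'
#' \eqn{sI_i = \mathrm{sign}(x_i - \bar x)\, I_i}, separating
#' high-expression neighborhoods (positive) from low-expression
#' neighborhoods (negative) for visualization. \code{sign(0)} is taken as 0.
#'
#' @inheritParams moransI
#' @return per-cell signed LISA values.
#' @export
signedLisa <- function(x, weights) {
    z <- .alignVec(x, weights)
    sign(z - mean(z)) * lisaScores(x, weights)
}

.lisaTestCore <- function(X, weights, alpha = 0.05,
                          null = c("conditional", "randomization")) {
    null <- match.arg(null)
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    .checkGraph(weights)
    X <- .alignMat(X, weights)
    n <- ncol(X)
    if (n <= 3) stop("LISA moments require N > 3 cells")
    const <- apply(X, 1L, function(r) max(r) == min(r))
    if (any(const)) stop("LISA is not defined for constant signals: ",
                         paste(head(rownames(X)[const], 5), collapse = ", "))
    W <- weights@W
    deg <- Matrix::rowSums(W)
    Z <- X - rowMeans(X)
    ss <- rowSums(Z^2)
    S <- as.matrix(Z %*% W)                       # S[g,i] = sum_j W_ij z_gj
    lisa <- (n / ss) * Z * S
    n1 <- n - 1
    degM <- matrix(deg, nrow(Z), n, byrow = TRUE)
    if (null == "conditional") {
        # x_i held fixed; S is a sum of deg_i draws without replacement from
        # the leave-one-out value population
        muP <- -Z / n1
        sigP2 <- (ss - Z^2) / n1 - muP^2
        ES <- degM * muP
        VS <- degM * sigP2 * (n1 - degM) / max(n1 - 1, 1)
        EI <- (n / ss) * Z * ES
        sdI <- (n / ss) * abs(Z) * sqrt(pmax(VS, 0))
        zstat <- (lisa - EI) / sdI
    } else {
        # total randomization (Anselin 1995): x_i random too
        b2 <- n * rowSums(Z^4) / ss^2
        EI <- -degM / n1
        VI <- degM * (n - b2) / n1 +
            (degM^2 - degM) * (2 * b2 - n) / (n1 * max(n - 2, 1)) -
            (degM / n1)^2
        zstat <- (lisa - EI) / sqrt(pmax(VI, 0))
    }
    p <- pnorm(zstat, lower.tail = FALSE)
    p[!is.finite(zstat)] <- 1                     # zero z_i or isolated cell
    list(lisa = lisa, pLocal = p,
         drivingFraction = setNames(rowMeans(p < alpha), rownames(X)),
         alpha = alpha, null = null)
}

#' Per-cell LISA significance and pattern scale
#'
#' Computes per-cell one-sided p-values from the conditional-randomization
#' LISA moments and summarizes each gene by its driving fraction: the
#' proportion of cells whose local association is individually significant
#' at \code{alpha}. Per-cell p-values are deliberately not
#' multiplicity-corrected; they feed a fraction, not a discovery claim.
#'
#' @param x genes x cells matrix, per-cell numeric vector, or
#'   \code{\link{SpatialExpressionSet}}.
#' @param weights a \code{\link{SpatialWeights}}.
#' @param alpha per-cell significance level in (0, 1); default 0.05.
#' @param null per-cell null model: \code{"conditional"} (default) holds the
#'   cell's own value fixed and permutes the remaining values, matching a
#'   conditional-permutation reference; \code{"randomization"} uses the
#'   classical total-randomization moments in which the cell's own value is
#'   also exchangeable. The conditional flavor is calibrated per cell; the
#'   randomization flavor requires the product of a cell's deviation and its
#'   neighborhood's deviation to be jointly extreme and is therefore more
#'   conservative toward isolated spikes.
#' @param ... passed between methods.
#' @return list with matrices \code{lisa} and \code{pLocal} (genes x cells)
#'   and the named vector \code{drivingFraction}.
#' @examples
#' pos <- simulatePositions(100, seed = 1)
#' sw <- delaunayAdjacency(pos)
#' sim <- simulatePatternGenes(pos, "two_blob", nGenes = 2, seed = 1)
#' lisaTest(sim$expr, sw)$drivingFraction
#' @export
setMethod("lisaTest", signature(x = "matrix", weights = "SpatialWeights"),
    function(x, weights, alpha = 0.05,
             null = c("conditional", "randomization"), ...)
        .lisaTestCore(x, weights, alpha, null))

#' @rdname lisaTest-matrix-SpatialWeights-method
#' @export
setMethod("lisaTest", signature(x = "numeric", weights = "SpatialWeights"),
    function(x, weights, alpha = 0.05,
             null = c("conditional", "randomization"), ...) {
        r <- .lisaTestCore(matrix(x, 1L, dimnames = list("x", names(x))),
                           weights, alpha, null)
        list(lisa = r$lisa[1L, ], pLocal = r$pLocal[1L, ],
             drivingFraction = unname(r$drivingFraction), alpha = alpha)
    })

#' @rdname lisaTest-matrix-SpatialWeights-method
#' @export
setMethod("lisaTest",
    signature(x = "SpatialExpressionSet", weights = "SpatialWeights"),
    function(x, weights, alpha = 0.05,
             null = c("conditional", "randomization"), ...)
        .lisaTestCore(as.matrix(SummarizedExperiment::assay(x)), weights,
                      alpha, null))

#' Select spatially heterogeneous genes of sufficient scale
#'
#' Combines the global and local screens: a gene is selected when its
#' BH-adjusted Moran p-value is below \code{pAdjMax} and its pattern is
#' driven by strictly more than \code{minFraction} of cells. The driving
#' fraction filter rejects statistically significant but tiny hotspot
#' artifacts.
#'
#' @param moran result of \code{\link{moranTest}}.
#' @param lisa result of \code{\link{lisaTest}} (or a named driving-fraction
#'   vector).
#' @param pAdjMax adjusted p-value threshold (strict; default 0.05).
#' @param minFraction driving-fraction threshold (strict; default 0.05).
#' @return character vector of selected gene ids.
#' @export
selectSpatialGenes <- function(moran, lisa, pAdjMax = 0.05,
                               minFraction = 0.05) {
    df <- if (is.list(lisa) && !is.null(lisa$drivingFraction))
        lisa$drivingFraction else lisa
    genes <- rownames(moran)
    if (!all(genes %in% names(df)))
        stop("moran and lisa results cover different genes")
    df <- df[genes]
    genes[moran$p.adj < pAdjMax & df > minFraction & is.finite(moran$p.adj)]
}
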