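#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal t isSymmetric diag rowSums colSums
#'   which readMM writeMM
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom stats pnorm p.adjust prcomp sd quantile var median rnorm runif
#'   rpois setNames wilcox.test hclust as.dist cutree dist
#' @importFrom utils read.table write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom Rcpp sourceCpp
#' @useDynLib SpatialScreen, .registration = TRUE
NULL

#' Binary spatial adjacency weights
#'
#' \code{SpatialWeights} holds the binary, symmetric, zero-diagonal N x N
#' neighbor matrix \eqn{W} built from a Delaunay triangulation of cell
#' positions (optionally pruned by edge length), together with a construction
#' record. This matrix is the density-agnostic spatial representation on
#' which every statistic in the package operates: \eqn{W_{ij} = 1} if cells
#' \eqn{i} and \eqn{j} are spatial neighbors and 0 otherwise.
#'
#' @slot W a sparse \code{dgCMatrix} with entries in \{0, 1\}, symmetric with
#'   zero diagonal; dimnames carry the cell identifiers.
#' @slot meta list recording how the matrix was built (dimensionality,
#'   pruning threshold, jitter seed, coordinates, isolated cells).
#'
#' @seealso \code{\link{delaunayAdjacency}}, \code{\link{pruneLongEdges}}
#' @export
setClass("SpatialWeights",
         slots = c(W = "dgCMatrix", meta = "list"))

setValidity("SpatialWeights", function(object) {
    W <- object@W
    if (nrow(W) != ncol(W)) return("W must be square")
    if (is.null(rownames(W)) || is.null(colnames(W)))
        return("W must carry cell ids as dimnames")
    if (!identical(rownames(W), colnames(W)))
        return("row and column ids must agree")
    if (anyDuplicated(rownames(W))) return("cell ids must be unique")
    if (length(W@x) && !all(W@x %in% c(0, 1)))
        return("entries of W must be 0 or 1")
    if (any(Matrix::diag(W) != 0)) return("diagonal of W must be zero")
    if (!Matrix::isSymmetric(W)) return("W must be symmetric")
    TRUE
})

#' Construct a SpatialWeights object from an adjacency matrix
#'
#' Low-level constructor for a pre-built binary symmetric adjacency matrix
#' (e.g. a hand-specified graph); most users should build weights from
#' positions with \code{\link{delaunayAdjacency}}.
#'
#' @param W square binary symmetric matrix with zero diagonal; rownames are
#'   used as cell ids (generated when absent).
#' @param coords optional matching coordinate matrix, kept for pruning and
#'   interpolation.
#' @return a \code{\link{SpatialWeights}}.
#' @examples
#' W <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)  # path a-b-c
#' sw <- SpatialWeights(W)
#' @export
SpatialWeights <- function(W, coords = NULL) {
    W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    W <- methods::as(W * 1, "dgCMatrix")
    if (is.null(rownames(W)))
        dimnames(W) <- rep(list(sprintf("cell%d", seq_len(nrow(W)))), 2)
    if (!is.null(coords)) rownames(coords) <- rownames(W)
    methods::new("SpatialWeights", W = W,
                 meta = list(dim = if (is.null(coords)) NA_integer_
                             else ncol(coords),
                             coords = coords, pruneDist = Inf,
                             isolated = rownames(W)[Matrix::rowSums(W) == 0]))
}

#' Inter-cell-type adjacency weights
#'
#' Rectangular restriction of a \code{\link{SpatialWeights}} matrix to the
#' edges linking cells of one type (rows) to cells of another type
#' (columns). \eqn{W^{ict}_{ij} = 1} when the i-th type-A cell and the j-th
#' type-B cell are spatial neighbors in the parent graph. Used by the
#' inter-cell-type spatial cross-correlation (\code{\link{interTypeCrossCor}}).
#'
#' @slot W sparse |A| x |B| binary matrix; dimnames carry cell ids.
#' @slot typeA,typeB the two cell-type labels.
#' @slot meta list (parent construction record, edge count).
#' @export
setClass("InterTypeWeights",
         slots = c(W = "dgCMatrix", typeA = "character", typeB = "character",
                   meta = "list"))

setValidity("InterTypeWeights", function(object) {
    W <- object@W
    if (length(W@x) && !all(W@x %in% c(0, 1)))
        return("entries must be 0 or 1")
    if (is.null(rownames(W)) || is.null(colnames(W)))
        return("W must carry cell ids as dimnames")
    TRUE
})

#' Spatially resolved expression container
#'
#' A thin \code{SummarizedExperiment} subclass binding a genes x cells
#' expression assay to per-cell spatial coordinates (columns \code{x},
#' \code{y}, optional \code{z}), optional \code{section} labels for
#' multilayer data, optional \code{cellType} annotations, and optional
#' per-cell \code{volume} for imaging-based normalization. A
#' \code{normalization} entry in \code{metadata()} records which
#' normalization has been applied.
#'
#' @export
setClass("SpatialExpressionSet", contains = "SummarizedExperiment")

setValidity("SpatialExpressionSet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    for (col in c("x", "y")) {
        if (!col %in% colnames(cd)) return(sprintf("colData must contain '%s'", col))
        if (any(!is.finite(cd[[col]]))) return(sprintf("non-finite '%s' coordinate", col))
    }
    if ("z" %in% colnames(cd) && any(!is.finite(cd$z)))
        return("non-finite 'z' coordinate")
    if (anyDuplicated(colnames(object))) return("cell ids must be unique")
    TRUE
})

#' Construct a SpatialExpressionSet
#'
#' @param counts genes x cells matrix (dense or sparse) of raw counts or
#'   pre-normalized values; rownames are gene ids, colnames cell ids.
#' @param coords N x 2 or N x 3 numeric matrix (or data.frame with columns
#'   \code{x}, \code{y}\[, \code{z}\]) of spatial positions, rows aligned to
#'   the columns of \code{counts} (matched by name when rownames are present).
#' @param section optional per-cell section labels for multilayer data.
#' @param cellType optional per-cell type annotations.
#' @param volume optional strictly positive per-cell imaged volumes.
#'
#' @return a \code{\link{SpatialExpressionSet}}.
#' @examples
#' pos <- simulatePositions(60, seed = 1)
#' expr <- simulateNullGenes(pos, nGenes = 5, seed = 1)
#' se <- SpatialExpressionSet(expr, pos)
#' @export
SpatialExpressionSet <- function(counts, coords, section = NULL,
                                 cellType = NULL, volume = NULL) {
    coords <- .asCoords(coords)
    if (is.null(colnames(counts)))
        stop("counts must have cell ids as colnames")
    if (!is.null(rownames(coords))) {
        miss <- setdiff(colnames(counts), rownames(coords))
        if (length(miss))
            stop("cells missing from coords: ", paste(head(miss, 5), collapse = ", "))
        coords <- coords[colnames(counts), , drop = FALSE]
    } else if (nrow(coords) != ncol(counts)) {
        stop("coords rows must match counts columns")
    }
    cd <- S4Vectors::DataFrame(x = coords[, 1], y = coords[, 2],
                               row.names = colnames(counts))
    if (ncol(coords) == 3) cd$z <- coords[, 3]
    if (!is.null(section)) cd$section <- section
    if (!is.null(cellType)) cd$cellType <- cellType
    if (!is.null(volume)) {
        if (any(!is.finite(volume)) || any(volume <= 0))
            stop("volumes must be strictly positive and finite")
        cd$volume <- volume
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = counts), colData = cd)
    se <- methods::as(se, "SpatialExpressionSet")
    S4Vectors::metadata(se)$normalization <- "none"
    methods::validObject(se)
    se
}
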