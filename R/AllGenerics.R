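#' @describeIn SpatialWeights number of cells
#' @param x,object a \code{SpatialWeights}
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @describeIn SpatialWeights cell identifiers
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @describeIn SpatialWeights the sparse binary weight matrix
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @describeIn SpatialWeights total weight \eqn{\sum_{ij} W_{ij}} (twice the
#'   number of undirected edges)
#' @export
setGeneric("totalWeight", function(x) standardGeneric("totalWeight"))

#' @describeIn SpatialWeights two-column matrix of undirected edges
#'   (each once, by index i < j)
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @export
setGeneric("normalizeCPM", function(x, ...) standardGeneric("normalizeCPM"))

#' @export
setGeneric("normalizeVolume",
           function(x, volumes, ...) standardGeneric("normalizeVolume"))

#' @export
setGeneric("delaunayAdjacency",
           function(x, ...) standardGeneric("delaunayAdjacency"))

#' @export
setGeneric("moranTest",
           function(x, weights, ...) standardGeneric("moranTest"))

#' @export
setGeneric("lisaTest",
           function(x, weights, ...) standardGeneric("lisaTest"))

setMethod("nCells", "SpatialWeights", function(x) nrow(x@W))
setMethod("cellIds", "SpatialWeights", function(x) rownames(x@W))
setMethod("weightMatrix", "SpatialWeights", function(x) x@W)
setMethod("totalWeight", "SpatialWeights", function(x) sum(x@W))
setMethod("edgeList", "SpatialWeights", function(x) .edgeIdx(x@W))

setMethod("weightMatrix", "InterTypeWeights", function(x) x@W)
setMethod("totalWeight", "InterTypeWeights", function(x) sum(x@W))

setMethod("spatialCoords", "SpatialExpressionSet", function(x) {
    cd <- SummarizedExperiment::colData(x)
    cols <- c("x", "y", if ("z" %in% colnames(cd)) "z")
    as.matrix(cd[, cols, drop = FALSE])
})

#' @export
setMethod("show", "SpatialWeights", function(object) {
    m <- object@meta
    cat(sprintf("SpatialWeights: %d cells, %d undirected edges (%dD)\n",
                nCells(object), sum(object@W) / 2,
                if (is.null(m$dim)) NA_integer_ else m$dim))
    if (!is.null(m$pruneDist) && is.finite(m$pruneDist))
        cat(sprintf("  pruned at distance %.4g (%d isolated cells)\n",
                    m$pruneDist, length(m$isolated)))
    invisible(object)
})

#' @export
setMethod("show", "InterTypeWeights", function(object) {
    cat(sprintf("InterTypeWeights: %d '%s' x %d '%s' cells, %d inter-type edges\n",
                nrow(object@W), object@typeA, ncol(object@W), object@typeB,
                sum(object@W)))
    invisible(object)
})

# undirected edge index pairs (i < j) of a symmetric sparse binary matrix
.edgeIdx <- function(W) {
    tr <- Matrix::which(W != 0, arr.ind = TRUE)
    tr <- tr[tr[, 1] < tr[, 2], , drop = FALSE]
    dimnames(tr) <- list(NULL, c("i", "j"))
    tr
}
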