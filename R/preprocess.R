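# Expression normalization and filtering. All downstream statistics assume
# expression magnitudes are technically comparable across cells, so raw
# sequencing counts go through CPM (no log) and imaging-based counts through
# per-cell volume normalization first.

.scaleColumns <- function(x, f) {
    if (methods::is(x, "Matrix")) x %*% Matrix::Diagonal(x = f, names = FALSE)
    else sweep(x, 2L, f, "*")
}

.cpm <- function(x) {
    cs <- if (methods::is(x, "Matrix")) Matrix::colSums(x) else colSums(x)
    if (any(x < 0)) stop("counts must be nonnegative")
    bad <- which(cs <= 0)
    if (length(bad))
        stop("cells with zero total counts: ",
             paste(head(colnames(x)[bad], 10), collapse = ", "))
    out <- .scaleColumns(x, 1e6 / cs)
    dimnames(out) <- dimnames(x)
    out
}

#' Counts-per-million normalization (no log transform)
#'
#' Scales every cell's column to sum to \eqn{10^6}. No log transform is
#' applied: the autocorrelation statistics operate on normalized magnitudes
#' directly. Zeros and within-cell rank order are preserved exactly.
#'
#' @param x genes x cells matrix of raw nonnegative counts, or a
#'   \code{\link{SpatialExpressionSet}} (whose \code{normalization} record is
#'   updated; re-normalizing an already-normalized object only warns).
#' @param ... unused.
#' @return object of the same class with normalized values.
#' @examples
#' normalizeCPM(matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), "c1")))
#' @export
setMethod("normalizeCPM", "ANY", function(x, ...) .cpm(x))

#' @rdname normalizeCPM-ANY-method
#' @export
setMethod("normalizeCPM", "SpatialExpressionSet", function(x, ...) {
    rec <- S4Vectors::metadata(x)$normalization
    if (!is.null(rec) && !identical(rec, "none"))
        warning("expression already normalized ('", rec, "'); re-normalizing")
    SummarizedExperiment::assay(x) <- .cpm(SummarizedExperiment::assay(x))
    S4Vectors::metadata(x)$normalization <- "cpm"
    x
})

.volnorm <- function(x, volumes) {
    if (length(volumes) != ncol(x))
        stop("one volume per cell required (", ncol(x), " cells, ",
             length(volumes), " volumes)")
    if (any(!is.finite(volumes)) || any(volumes <= 0))
        stop("volumes must be strictly positive and finite")
    out <- .scaleColumns(x, 1 / volumes)
    dimnames(out) <- dimnames(x)
    out
}

#' Per-cell volume normalization for imaging-based data
#'
#' Divides each cell's counts by its imaged volume, the appropriate
#' normalization for segmentation-based in situ measurements where detection
#' scales with cell size rather than library depth.
#'
#' @param x genes x cells matrix or \code{\link{SpatialExpressionSet}}.
#' @param volumes strictly positive per-cell volumes (taken from
#'   \code{colData(x)$volume} when omitted for a SpatialExpressionSet).
#' @param ... unused.
#' @return normalized object of the same class.
#' @export
setMethod("normalizeVolume", "ANY", function(x, volumes, ...) .volnorm(x, volumes))

#' @rdname normalizeVolume-ANY-method
#' @export
setMethod("normalizeVolume", "SpatialExpressionSet", function(x, volumes, ...) {
    if (missing(volumes)) {
        volumes <- SummarizedExperiment::colData(x)$volume
        if (is.null(volumes)) stop("no 'volume' column in colData(x)")
    }
    rec <- S4Vectors::metadata(x)$normalization
    if (!is.null(rec) && !identical(rec, "none"))
        warning("expression already normalized ('", rec, "'); re-normalizing")
    SummarizedExperiment::assay(x) <- .volnorm(SummarizedExperiment::assay(x), volumes)
    S4Vectors::metadata(x)$normalization <- "volume"
    x
})

#' Drop genes without expression variability
#'
#' Moran's I is undefined for constant signals, so genes with zero variance
#' across cells are removed before testing. The removed genes are reported
#' via \code{message()} and attached as \code{attr(, "dropped")}.
#'
#' @param x genes x cells matrix.
#' @return the matrix restricted to variable genes (possibly zero rows, with
#'   a warning).
#' @export
dropInvariantGenes <- function(x) {
    x <- as.matrix(x)
    rng <- cbind(apply(x, 1L, min), apply(x, 1L, max))
    keep <- rng[, 1] < rng[, 2]
    dropped <- rownames(x)[!keep]
    if (length(dropped))
        message("dropping ", length(dropped), " invariant gene(s)")
    if (!any(keep)) warning("all genes are constant; empty matrix returned")
    out <- x[keep, , drop = FALSE]
    attr(out, "dropped") <- dropped
    out
}

#' Detection filter for well-detected genes
#'
#' Keeps genes expressed (value strictly greater than 0) in strictly more
#' than \code{minCells} cells. The strict inequality follows the
#' "more than 30 cells" convention (a gene nonzero in exactly
#' \code{minCells} cells is excluded).
#'
#' @param x genes x cells matrix (typically CPM-normalized).
#' @param minCells nonnegative integer threshold (default 30).
#' @return character vector of retained gene ids.
#' @export
detectionFilter <- function(x, minCells = 30L) {
    if (minCells < 0) stop("minCells must be >= 0")
    n <- if (methods::is(x, "Matrix")) Matrix::rowSums(x > 0) else rowSums(x > 0)
    rownames(x)[n > minCells]
}
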