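# Spatial adjacency construction: Delaunay triangulation within sections,
# optional distance pruning, inter-cell-type restriction, mutual-nearest-
# neighbor pairing across serial sections, and graph geodesic distances.

# coerce positions (matrix / data.frame with x,y[,z] columns) to a numeric
# matrix with cell ids as rownames
.asCoords <- function(x) {
    if (is.data.frame(x)) {
        cols <- intersect(c("x", "y", "z"), colnames(x))
        if (length(cols) >= 2) {
            m <- as.matrix(x[, cols, drop = FALSE])
        } else {
            m <- as.matrix(x[, vapply(x, is.numeric, logical(1)), drop = FALSE])
        }
        rownames(m) <- rownames(x)
        x <- m
    }
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (!ncol(x) %in% c(2L, 3L))
        stop("positions must have 2 or 3 coordinate columns")
    if (any(!is.finite(x))) stop("non-finite coordinates")
    if (is.null(rownames(x)))
        rownames(x) <- sprintf("cell%d", seq_len(nrow(x)))
    if (anyDuplicated(rownames(x))) stop("cell ids must be unique")
    x
}

.bboxDiag <- function(coords) {
    sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
}

.buildW <- function(ei, ej, ids) {
    n <- length(ids)
    Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = 1,
                         dims = c(n, n), dimnames = list(ids, ids))
}

.delaunayCore <- function(coords, prune = Inf, jitter = FALSE,
                          jitterSeed = 0L) {
    n <- nrow(coords)
    d <- ncol(coords)
    if (n < d + 1L)
        stop(sprintf("need at least %d points for %dD triangulation, got %d",
                     d + 1L, d, n))
    if (anyDuplicated(coords) && !jitter)
        stop("duplicate coordinates: the Voronoi diagram is undefined; ",
             "set jitter = TRUE to break ties deterministically")
    used <- coords
    if (jitter) {
        eps <- 1e-9 * .bboxDiag(coords)
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        set.seed(jitterSeed)
        used <- coords + matrix(runif(n * d, -eps, eps), n, d)
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    if (qr(scale(used, center = TRUE, scale = FALSE))$rank < d)
        stop(if (d == 2L) "points are collinear: " else "points are coplanar: ",
             "Delaunay triangulation is degenerate")
    if (d == 2L) {
        dd <- deldir::deldir(used[, 1], used[, 2])
        ed <- as.matrix(dd$delsgs[, c("ind1", "ind2")])
    } else {
        ed <- .delaunay3dEdges(used)
    }
    ei <- pmin(ed[, 1], ed[, 2])
    ej <- pmax(ed[, 1], ed[, 2])
    W <- .buildW(ei, ej, rownames(coords))
    sw <- methods::new("SpatialWeights", W = W,
                       meta = list(dim = d, coords = coords,
                                   jitter = jitter,
                                   jitterSeed = if (jitter) jitterSeed else NA,
                                   pruneDist = Inf, isolated = character(0)))
    if (!identical(prune, Inf) && !is.null(prune))
        sw <- pruneLongEdges(sw, maxDist = prune)
    sw
}

#' Delaunay adjacency graph of cell positions
#'
#' Builds the binary spatial adjacency matrix \eqn{W}: two cells are
#' neighbors iff they share an edge of the Delaunay triangulation of the
#' positions (equivalently, iff their Voronoi polyhedra share a facet).
#' Works for 2D and 3D positions. Because the representation is binary it is
#' insensitive to local cell density, which is what makes the downstream
#' autocorrelation statistics density-agnostic.
#'
#' Grid-like (cocircular) inputs have ties whose resolution is
#' backend-dependent; \code{jitter = TRUE} breaks them deterministically by
#' displacing each coordinate by at most \eqn{10^{-9}} of the bounding-box
#' diagonal using \code{jitterSeed}.
#'
#' @param x cell positions: an N x 2 or N x 3 matrix (rownames = cell ids),
#'   a data.frame with columns \code{x}, \code{y}\[, \code{z}\], or a
#'   \code{\link{SpatialExpressionSet}}.
#' @param prune maximum admissible edge length: a positive number,
#'   \code{"auto"} (drop edges longer than Q3 + 1.5 IQR of the edge-length
#'   distribution), or \code{Inf} for no pruning (default).
#' @param jitter logical; deterministically jitter coordinates to break
#'   degenerate ties (also required to accept duplicated positions).
#' @param jitterSeed integer seed for the jitter displacements, recorded in
#'   the construction metadata.
#' @param ... passed between methods.
#'
#' @return a \code{\link{SpatialWeights}} object.
#' @examples
#' pos <- simulatePositions(100, seed = 1)
#' sw <- delaunayAdjacency(pos, prune = "auto")
#' sw
#' @export
setMethod("delaunayAdjacency", "matrix",
    function(x, prune = Inf, jitter = FALSE, jitterSeed = 0L, ...) {
        .delaunayCore(.asCoords(x), prune = prune, jitter = jitter,
                      jitterSeed = jitterSeed)
    })

#' @rdname delaunayAdjacency-matrix-method
#' @export
setMethod("delaunayAdjacency", "data.frame",
    function(x, prune = Inf, jitter = FALSE, jitterSeed = 0L, ...) {
        .delaunayCore(.asCoords(x), prune = prune, jitter = jitter,
                      jitterSeed = jitterSeed)
    })

#' @rdname delaunayAdjacency-matrix-method
#' @export
setMethod("delaunayAdjacency", "SpatialExpressionSet",
    function(x, prune = Inf, jitter = FALSE, jitterSeed = 0L, ...) {
        .delaunayCore(spatialCoords(x), prune = prune, jitter = jitter,
                      jitterSeed = jitterSeed)
    })

#' Remove implausibly long adjacency edges
#'
#' Delaunay triangulations connect hull cells across large empty regions;
#' for biological interpretability such long-range links can be dropped.
#' \code{"auto"} uses the scale-free outlier rule Q3 + 1.5 IQR on the
#' Delaunay edge-length distribution. Cells left without neighbors are
#' recorded in \code{meta(sw)$isolated}.
#'
#' @param weights a \code{\link{SpatialWeights}} object.
#' @param maxDist positive number or \code{"auto"}.
#' @param coords optional coordinates (defaults to those recorded at
#'   construction).
#' @return a pruned \code{\link{SpatialWeights}}; pruning is monotone (the
#'   result is entrywise <= the input) and preserves symmetry.
#' @examples
#' pos <- simulatePositions(100, seed = 1)
#' sw <- pruneLongEdges(delaunayAdjacency(pos))
#' @export
pruneLongEdges <- function(weights, maxDist = "auto", coords = NULL) {
    stopifnot(methods::is(weights, "SpatialWeights"))
    if (is.null(coords)) coords <- weights@meta$coords
    if (is.null(coords)) stop("no coordinates available for pruning")
    e <- .edgeIdx(weights@W)
    if (!nrow(e)) stop("weights has no edges to prune")
    len <- sqrt(rowSums((coords[e[, 1], , drop = FALSE] -
                         coords[e[, 2], , drop = FALSE])^2))
    if (identical(maxDist, "auto")) {
        q <- quantile(len, c(0.25, 0.75), names = FALSE)
        maxDist <- q[2] + 1.5 * (q[2] - q[1])
    }
    if (!is.numeric(maxDist) || length(maxDist) != 1L || maxDist <= 0)
        stop("maxDist must be a single positive number or \"auto\"")
    keep <- len <= maxDist
    if (!any(keep)) stop("pruning at maxDist = ", signif(maxDist, 4),
                         " would remove every edge")
    W <- .buildW(e[keep, 1], e[keep, 2], cellIds(weights))
    iso <- cellIds(weights)[Matrix::rowSums(W) == 0]
    if (length(iso))
        message(length(iso), " cell(s) left without neighbors after pruning")
    meta <- weights@meta
    meta$pruneDist <- maxDist
    meta$isolated <- iso
    methods::new("SpatialWeights", W = W, meta = meta)
}

#' Restrict adjacency to edges between two cell types
#'
#' Builds the rectangular inter-cell-type weight matrix \eqn{W^{ict}}:
#' \eqn{W^{ict}_{ij} = 1} iff the i-th cell of \code{typeA} and the j-th
#' cell of \code{typeB} are neighbors in the parent graph. Within-type edges
#' are excluded by construction (when \code{typeA != typeB}).
#'
#' @param weights a \code{\link{SpatialWeights}}.
#' @param types per-cell type labels, either named by cell id or aligned to
#'   \code{cellIds(weights)}.
#' @param typeA,typeB type labels present in \code{types}.
#' @return an \code{\link{InterTypeWeights}}; a warning is raised when no
#'   inter-type edge exists (downstream iSCI will refuse such input).
#' @examples
#' pos <- simulatePositions(100, seed = 1)
#' sw <- delaunayAdjacency(pos)
#' ty <- rep(c("A", "B"), length.out = 100)
#' itw <- interTypeAdjacency(sw, ty, "A", "B")
#' @export
interTypeAdjacency <- function(weights, types, typeA, typeB) {
    stopifnot(methods::is(weights, "SpatialWeights"))
    ids <- cellIds(weights)
    types <- as.character(if (!is.null(names(types))) types[ids] else types)
    if (length(types) != length(ids) || any(is.na(types)))
        stop("types must cover every cell in weights")
    for (ty in c(typeA, typeB))
        if (!ty %in% types) stop("unknown cell type label: ", ty)
    a <- ids[types == typeA]
    b <- ids[types == typeB]
    Wict <- weights@W[a, b, drop = FALSE]
    if (sum(Wict) == 0)
        warning("no inter-type edges between '", typeA, "' and '", typeB, "'")
    methods::new("InterTypeWeights", W = methods::as(Wict, "dgCMatrix"),
                 typeA = typeA, typeB = typeB,
                 meta = list(nEdges = sum(Wict), parent = weights@meta$dim))
}

#' Mutual-nearest-neighbor adjacency across serial sections
#'
#' For multilayer data where in-plane distances are much smaller than the
#' section spacing, consecutive sections are linked by mutual k-nearest
#' neighbors in the (x, y) plane: cells i (section s) and j (section s+1)
#' are adjacent iff each is among the other's k nearest in-plane neighbors.
#' Mutuality makes the relation symmetric by construction.
#'
#' @param x positions (matrix or data.frame, as in
#'   \code{\link{delaunayAdjacency}}); only the first two columns are used.
#' @param section per-cell section labels; ordering follows factor levels,
#'   or sorted unique values otherwise.
#' @param k number of in-plane nearest neighbors considered (default 6).
#' @return a \code{\link{SpatialWeights}} whose edges all join consecutive
#'   sections.
#' @examples
#' pos <- simulatePositions(60, layout = "multi_section", nSections = 2, seed = 1)
#' swx <- crossSectionAdjacency(pos, pos$section, k = 1)
#' @export
crossSectionAdjacency <- function(x, section, k = 6L) {
    coords <- .asCoords(x)[, 1:2, drop = FALSE]
    if (length(section) != nrow(coords))
        stop("section labels must align with positions")
    if (k < 1L) stop("k must be >= 1")
    lev <- if (is.factor(section)) levels(section) else sort(unique(section))
    lev <- lev[lev %in% as.character(section)]
    if (length(lev) < 2L)
        stop("cross-section adjacency requires at least two sections")
    section <- as.character(section)
    ei <- integer(0); ej <- integer(0)
    for (s in seq_len(length(lev) - 1L)) {
        ia <- which(section == lev[s])
        ib <- which(section == lev[s + 1L])
        ka <- min(k, length(ib)); kb <- min(k, length(ia))
        nnAB <- FNN::get.knnx(coords[ib, , drop = FALSE],
                              coords[ia, , drop = FALSE], k = ka)$nn.index
        nnBA <- FNN::get.knnx(coords[ia, , drop = FALSE],
                              coords[ib, , drop = FALSE], k = kb)$nn.index
        for (ai in seq_along(ia)) {
            for (bi in nnAB[ai, ]) {
                if (ai %in% nnBA[bi, ]) {
                    ei <- c(ei, ia[ai]); ej <- c(ej, ib[bi])
                }
            }
        }
    }
    if (!length(ei)) stop("no mutual nearest neighbors found across sections")
    W <- .buildW(pmin(ei, ej), pmax(ei, ej), rownames(coords))
    methods::new("SpatialWeights", W = W,
                 meta = list(dim = 2L, coords = coords, type = "cross_section_mnn",
                             k = k, section = section, pruneDist = Inf,
                             isolated = rownames(coords)[Matrix::rowSums(W) == 0]))
}

#' Graph geodesic (hop-count) distances
#'
#' Unweighted shortest-path distances on the adjacency graph: neighbors are
#' at distance 1, neighbors of neighbors at distance 2, and so forth.
#' Hop counts -- not Euclidean distances -- are the only spatial distance
#' used downstream, preserving density-agnosticism.
#'
#' @param weights a \code{\link{SpatialWeights}}.
#' @return an N x N numeric matrix of hop counts; 0 on the diagonal and
#'   \code{Inf} between disconnected components.
#' @examples
#' pos <- simulatePositions(50, seed = 1)
#' d <- geodesicDistances(delaunayAdjacency(pos))
#' @export
geodesicDistances <- function(weights) {
    stopifnot(methods::is(weights, "SpatialWeights"))
    g <- igraph::graph_from_adjacency_matrix(weights@W, mode = "undirected")
    igraph::distances(g)
}
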