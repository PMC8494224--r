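# Spatially informed graph-based clustering: a transcriptional kNN graph on
# principal components whose edges are re-weighted by graph-geodesic spatial
# proximity, weight = 1/(d + alpha) + beta, then partitioned by Louvain
# modularity optimization. Spatially close transcriptional neighbors gain
# weight; spatially unreachable ones keep the uniform floor beta (the
# d -> Inf limit), so disconnected components are never forced apart by the
# weighting alone.

#' Transcriptional k-nearest-neighbor graph
#'
#' PCA (centering only) on the normalized genes x cells matrix, then an
#' undirected graph connecting each cell with its k nearest Euclidean
#' neighbors in PC space. The union rule (an edge exists when either
#' endpoint lists the other) guarantees minimum degree k. Initial edge
#' weights are 1.
#'
#' @param x genes x cells matrix or \code{\link{SpatialExpressionSet}}.
#' @param nPcs number of principal components (default 30; reduced with a
#'   warning when fewer dimensions are available).
#' @param k number of nearest neighbors (default 30; must be < N).
#' @return an \code{igraph} graph with vertex names = cell ids and graph
#'   attributes \code{nPcs}, \code{k}.
#' @export
knnExpressionGraph <- function(x, nPcs = 30L, k = 30L) {
    if (methods::is(x, "SpatialExpressionSet"))
        x <- as.matrix(SummarizedExperiment::assay(x))
    x <- as.matrix(x)
    n <- ncol(x)
    if (k >= n) stop("k must be smaller than the number of cells")
    maxPcs <- min(nrow(x), n - 1L)
    if (nPcs > maxPcs) {
        warning("reducing nPcs from ", nPcs, " to ", maxPcs)
        nPcs <- maxPcs
    }
    pcs <- prcomp(t(x), center = TRUE, scale. = FALSE, rank. = nPcs)$x
    nn <- FNN::get.knn(pcs, k = k)$nn.index
    ei <- rep(seq_len(n), k)
    ej <- as.vector(nn)
    und <- cbind(pmin(ei, ej), pmax(ei, ej))
    und <- unique(und)
    g <- igraph::graph_from_edgelist(und, directed = FALSE)
    igraph::V(g)$name <- colnames(x)
    igraph::E(g)$weight <- 1
    g <- igraph::set_graph_attr(g, "nPcs", nPcs)
    igraph::set_graph_attr(g, "k", k)
}

#' Weight transcriptional edges by spatial proximity
#'
#' Replaces each edge weight with \code{1/(d + alpha) + beta}, where d is
#' the hop-count geodesic distance between the two cells on the spatial
#' adjacency graph. Unreachable pairs get the limiting weight \code{beta}.
#' \code{literal = TRUE} uses \code{(1/d + alpha) + beta} instead, the
#' alternative parenthesization in which alpha no longer bounds the weight
#' of near-zero distances.
#'
#' @param graph an \code{igraph} from \code{\link{knnExpressionGraph}}.
#' @param weights a \code{\link{SpatialWeights}} covering the graph's cells.
#' @param alpha positive pseudocount guarding against excessively large
#'   weights (default 1).
#' @param beta nonnegative uniform floor guarding against vanishing weights
#'   (default 1).
#' @param literal use the literal alternative parenthesization.
#' @return the graph with updated edge weights and recorded
#'   \code{alpha}/\code{beta} attributes.
#' @export
spatialEdgeWeights <- function(graph, weights, alpha = 1, beta = 1,
                               literal = FALSE) {
    if (alpha <= 0) stop("alpha must be > 0")
    if (beta < 0) stop("beta must be >= 0")
    ids <- igraph::V(graph)$name
    if (!all(ids %in% cellIds(weights)))
        stop("graph contains cells absent from the spatial weights")
    d <- geodesicDistances(weights)[ids, ids]
    ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
    dEdge <- d[cbind(ends[, 1], ends[, 2])]
    w <- if (literal) (1 / dEdge + alpha) + beta else 1 / (dEdge + alpha) + beta
    w[!is.finite(dEdge)] <- beta
    igraph::E(graph)$weight <- w
    graph <- igraph::set_graph_attr(graph, "alpha", alpha)
    igraph::set_graph_attr(graph, "beta", beta)
}

#' Louvain partition of a weighted cell graph
#'
#' Modularity-optimizing community detection on the (spatially weighted)
#' transcriptional graph. Deterministic given \code{seed}.
#'
#' @param graph an \code{igraph} with positive edge weights.
#' @param seed integer seed (default 0).
#' @return named integer vector mapping cell id to cluster.
#' @export
louvainCluster <- function(graph, seed = 0L) {
    if (igraph::vcount(graph) == 0) stop("empty graph")
    set.seed(seed)
    cl <- igraph::cluster_louvain(graph, weights = igraph::E(graph)$weight)
    setNames(igraph::membership(cl), igraph::V(graph)$name)
}

#' Differential-expression check for a spatially split cluster
#'
#' Spatially informed clustering can split a cluster into spatially
#' distinct subpopulations; this guardrail asks whether the two children
#' also differ transcriptionally. Runs a rank-based (Wilcoxon) two-sample
#' test per gene with BH correction.
#'
#' @param x genes x cells matrix.
#' @param cellsA,cellsB disjoint cell id vectors (>= 3 cells each) for the
#'   two children.
#' @return \code{DataFrame} with \code{statistic}, \code{p.value},
#'   \code{p.adj} per gene, ordered by p-value.
#' @export
validateSplitDE <- function(x, cellsA, cellsB) {
    x <- as.matrix(x)
    if (length(intersect(cellsA, cellsB)))
        stop("children must be disjoint cell sets")
    if (length(cellsA) < 3L || length(cellsB) < 3L)
        stop("each child needs at least 3 cells")
    if (!all(c(cellsA, cellsB) %in% colnames(x)))
        stop("unknown cell ids")
    a <- x[, cellsA, drop = FALSE]
    b <- x[, cellsB, drop = FALSE]
    tests <- lapply(seq_len(nrow(x)), function(g)
        suppressWarnings(wilcox.test(a[g, ], b[g, ], exact = FALSE)))
    p <- vapply(tests, `[[`, numeric(1), "p.value")
    out <- S4Vectors::DataFrame(
        statistic = vapply(tests, `[[`, numeric(1), "statistic"),
        p.value = p, p.adj = p.adjust(p, method = "BH"),
        row.names = rownames(x))
    out[order(out$p.value), ]
}
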