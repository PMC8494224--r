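# Readers and writers for the standard on-disk formats: MatrixMarket
# expression with gene/cell sidecars, dense CSV/TSV expression, positions
# and annotation tables, and edge-list adjacency exports. Cell ids are
# matched by exact string equality throughout.

.sepFor <- function(path, format = "auto") {
    if (format == "csv") return(",")
    if (format == "tsv") return("\t")
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a genes x cells expression matrix
#'
#' MatrixMarket input (\code{format = "mtx"}) expects gene and cell id
#' sidecar files (one id per line; defaults \code{genes.tsv} /
#' \code{cells.tsv} next to the matrix) and stays sparse. Dense CSV/TSV
#' input expects gene rows, a header of cell ids and the gene id in the
#' first column.
#'
#' @param path matrix file.
#' @param format \code{"auto"} (by extension), \code{"mtx"}, \code{"csv"}
#'   or \code{"tsv"}.
#' @param genesFile,cellsFile sidecar paths for MTX input.
#' @return a genes x cells matrix (sparse for MTX input).
#' @export
readExpression <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                           genesFile = NULL, cellsFile = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0) stop("empty expression file: ", path)
    if (format == "auto")
        format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
                  else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
                  else "tsv"
    if (format == "mtx") {
        if (is.null(genesFile)) genesFile <- file.path(dirname(path), "genes.tsv")
        if (is.null(cellsFile)) cellsFile <- file.path(dirname(path), "cells.tsv")
        for (f in c(genesFile, cellsFile))
            if (!file.exists(f)) stop("missing sidecar file: ", f)
        m <- Matrix::readMM(path)
        genes <- readLines(genesFile)
        cells <- readLines(cellsFile)
        if (nrow(m) != length(genes))
            stop("matrix has ", nrow(m), " rows but ", length(genes),
                 " gene ids in ", genesFile)
        if (ncol(m) != length(cells))
            stop("matrix has ", ncol(m), " columns but ", length(cells),
                 " cell ids in ", cellsFile)
        dimnames(m) <- list(genes, cells)
        return(methods::as(m, "CsparseMatrix"))
    }
    df <- read.table(path, header = TRUE, sep = .sepFor(path, format),
                     row.names = 1L, check.names = FALSE,
                     stringsAsFactors = FALSE)
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad))
        stop("non-numeric expression column(s): ",
             paste(colnames(df)[head(bad, 5)], collapse = ", "))
    as.matrix(df)
}

#' Read cell positions
#'
#' CSV/TSV with a header and columns \code{cell}, \code{x}, \code{y},
#' optional \code{z} and \code{section}.
#'
#' @param path positions file.
#' @return data.frame with numeric coordinate columns (plus
#'   \code{section} when present); rownames are cell ids.
#' @export
readPositions <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- read.table(path, header = TRUE, sep = .sepFor(path),
                     check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("cell", "x", "y")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("positions file lacks column(s): ",
                           paste(miss, collapse = ", "))
    if (anyDuplicated(df$cell)) stop("duplicate cell ids in positions file")
    rownames(df) <- as.character(df$cell)
    keep <- intersect(c("x", "y", "z", "section"), colnames(df))
    out <- df[, keep, drop = FALSE]
    for (col in intersect(c("x", "y", "z"), keep)) {
        out[[col]] <- as.numeric(out[[col]])
        if (any(!is.finite(out[[col]])))
            stop("non-finite '", col, "' coordinate in positions file")
    }
    out
}

#' Read per-cell type annotations
#'
#' TSV/CSV with header columns \code{cell} and \code{type}.
#'
#' @param path annotation file.
#' @return named character vector of types.
#' @export
readCellTypes <- function(path) {
    df <- read.table(path, header = TRUE, sep = .sepFor(path),
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("cell", "type") %in% colnames(df)))
        stop("cell type file needs columns 'cell' and 'type'")
    setNames(as.character(df$type), as.character(df$cell))
}

#' Read a receptor-ligand pair table
#'
#' TSV with header columns \code{receptor} and \code{ligand}; duplicate
#' pairs are rejected.
#'
#' @param path pair table file.
#' @return data.frame with \code{receptor} and \code{ligand} columns.
#' @export
readPairs <- function(path) {
    df <- read.table(path, header = TRUE, sep = .sepFor(path),
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("receptor", "ligand") %in% colnames(df)))
        stop("pair table needs columns 'receptor' and 'ligand'")
    if (anyDuplicated(df[, c("receptor", "ligand")]))
        stop("duplicate receptor-ligand pairs")
    df
}

#' Export adjacency as an edge list
#'
#' Writes each undirected edge once as \code{cell_i<TAB>cell_j}, pairs
#' ordered lexicographically within and across rows (deterministic output).
#'
#' @param weights a \code{\link{SpatialWeights}}.
#' @param path output file.
#' @export
writeEdgeList <- function(weights, path) {
    e <- edgeList(weights)
    ids <- cellIds(weights)
    a <- ids[e[, 1]]; b <- ids[e[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    o <- order(a, b)
    write.table(data.frame(a[o], b[o]), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Export adjacency as a MatrixMarket pattern file
#'
#' @param weights a \code{\link{SpatialWeights}}.
#' @param path output \code{.mtx} file.
#' @export
writeAdjacencyMM <- function(weights, path) {
    Matrix::writeMM(weightMatrix(weights), path)
    invisible(path)
}

#' Align expression, positions and annotations by cell id
#'
#' Intersects the cell ids, orders everything by the positions table, and
#' reports dropped cells. Errors when the intersection is empty.
#'
#' @param expr genes x cells matrix.
#' @param positions positions data.frame (rownames = cell ids).
#' @param types optional named type vector.
#' @param volumes optional named volume vector.
#' @return list with aligned \code{expr}, \code{positions}, \code{types},
#'   \code{volumes}.
#' @export
alignInputs <- function(expr, positions, types = NULL, volumes = NULL) {
    ids <- intersect(rownames(positions), colnames(expr))
    if (!length(ids)) stop("no shared cell ids between expression and positions")
    dropPos <- setdiff(rownames(positions), ids)
    dropExp <- setdiff(colnames(expr), ids)
    if (length(dropPos))
        message("dropping ", length(dropPos), " cell(s) without expression")
    if (length(dropExp))
        message("dropping ", length(dropExp), " cell(s) without positions")
    ids <- rownames(positions)[rownames(positions) %in% ids]  # position order
    out <- list(expr = expr[, ids, drop = FALSE],
                positions = positions[ids, , drop = FALSE],
                types = if (!is.null(types)) types[ids],
                volumes = if (!is.null(volumes)) volumes[ids])
    out
}

#' Write the combined autocorrelation result table
#'
#' Deterministic TSV with columns \code{gene}, \code{moran_i},
#' \code{expected}, \code{variance}, \code{z}, \code{p}, \code{p_adj},
#' \code{driving_fraction}, \code{selected}, at full float precision.
#'
#' @param moran result of \code{\link{moranTest}}.
#' @param lisa result of \code{\link{lisaTest}} over the same genes.
#' @param path output file.
#' @param pAdjMax,minFraction selection thresholds (see
#'   \code{\link{selectSpatialGenes}}).
#' @export
writeAutocorrResults <- function(moran, lisa, path, pAdjMax = 0.05,
                                 minFraction = 0.05) {
    sel <- selectSpatialGenes(moran, lisa, pAdjMax, minFraction)
    df <- data.frame(gene = rownames(moran),
                     moran_i = moran$observed, expected = moran$expected,
                     variance = moran$variance, z = moran$z,
                     p = moran$p.value, p_adj = moran$p.adj,
                     driving_fraction = lisa$drivingFraction[rownames(moran)],
                     selected = rownames(moran) %in% sel)
    write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
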