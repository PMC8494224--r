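# Synthetic-data generators. These emulate the statistical structure the
# statistics are designed for -- spatial point patterns of varying density,
# patterned and null genes with count noise, tiny-hotspot artifacts,
# multi-section layouts, and two-cell-type communication scenarios -- so the
# whole pipeline is testable without any external dataset. Every generator
# is a pure function of its arguments and seed.

.simSpec <- function(...) list(...)

#' Simulate spatial cell positions
#'
#' Layouts: \code{"uniform"} (homogeneous in the unit square),
#' \code{"density_gradient"} (x-intensity proportional to
#' \code{exp(gradientRate * x)}), \code{"distorted"} (uniform positions
#' warped by the monotone map \code{x -> x^gammaWarp}), \code{"multi_section"}
#' (one base layout replicated across sections with i.i.d. jitter), and
#' \code{"two_islands"} (two equal uniform blocks separated by an empty gap,
#' for split-cluster scenarios).
#'
#' @param nCells total number of cells (>= 10).
#' @param layout one of the layouts above.
#' @param seed integer seed.
#' @param gammaWarp warp exponent for \code{"distorted"} (default 2;
#'   1 is the identity).
#' @param gradientRate exponential rate for \code{"density_gradient"}
#'   (default 2).
#' @param nSections,sectionJitter sections and per-cell coordinate jitter sd
#'   for \code{"multi_section"}.
#' @param islandGap empty horizontal gap between the two islands (default 1,
#'   i.e. one full island width).
#' @return data.frame with columns \code{x}, \code{y} (plus \code{section}
#'   or \code{island} where applicable); rownames are cell ids and the
#'   generating specification is attached as \code{attr(, "simSpec")}.
#' @examples
#' head(simulatePositions(100, "density_gradient", seed = 1))
#' @export
simulatePositions <- function(nCells, layout = c("uniform", "density_gradient",
                                                 "distorted", "multi_section",
                                                 "two_islands"),
                              seed = 0L, gammaWarp = 2, gradientRate = 2,
                              nSections = 2L, sectionJitter = 0.01,
                              islandGap = 1) {
    layout <- match.arg(layout)
    if (nCells < 10L) stop("nCells must be >= 10")
    set.seed(seed)
    out <- switch(layout,
        uniform = data.frame(x = runif(nCells), y = runif(nCells)),
        density_gradient = {
            c0 <- gradientRate
            u <- runif(nCells)
            data.frame(x = log(1 + u * (exp(c0) - 1)) / c0, y = runif(nCells))
        },
        distorted = data.frame(x = runif(nCells)^gammaWarp, y = runif(nCells)),
        multi_section = {
            nPer <- ceiling(nCells / nSections)
            base <- cbind(runif(nPer), runif(nPer))
            df <- do.call(rbind, lapply(seq_len(nSections), function(s)
                data.frame(x = base[, 1] + rnorm(nPer, 0, sectionJitter),
                           y = base[, 2] + rnorm(nPer, 0, sectionJitter),
                           section = sprintf("s%d", s))))
            df[seq_len(nCells), ]
        },
        two_islands = {
            n1 <- floor(nCells / 2); n2 <- nCells - n1
            data.frame(x = c(runif(n1), runif(n2) + 1 + islandGap),
                       y = runif(nCells),
                       island = rep(c("island1", "island2"), c(n1, n2)))
        })
    rownames(out) <- sprintf("cell%d", seq_len(nrow(out)))
    attr(out, "simSpec") <- .simSpec(layout = layout, nCells = nCells,
                                     seed = seed, gammaWarp = gammaWarp,
                                     gradientRate = gradientRate,
                                     nSections = nSections,
                                     sectionJitter = sectionJitter,
                                     islandGap = islandGap)
    out
}

.noiseMatrix <- function(nGenes, n, noise, meanExpr, libSizeSd, meanSurface) {
    # meanSurface: nGenes x n standardized mean surfaces (0 for null genes)
    if (noise == "gaussian") {
        meanSurface + matrix(rnorm(nGenes * n), nGenes, n)
    } else {
        libf <- exp(rnorm(n, 0, libSizeSd))
        lam <- meanExpr * exp(0.3 * meanSurface) *
            matrix(libf, nGenes, n, byrow = TRUE)
        matrix(rpois(nGenes * n, lam), nGenes, n)
    }
}

#' Simulate spatially unstructured (null) genes
#'
#' Values are i.i.d. per cell -- Gaussian by default, or Poisson counts with
#' log-normal per-cell library factors -- so any apparent spatial
#' aggregation is an artifact of cell placement, never of the expression
#' mechanism.
#'
#' @param positions positions data.frame from \code{\link{simulatePositions}}
#'   (only its rownames/size are used).
#' @param nGenes number of genes.
#' @param noise \code{"gaussian"} (sd 1) or \code{"poisson"}.
#' @param seed integer seed.
#' @param meanExpr Poisson mean at baseline (default 5).
#' @param libSizeSd sd of the log-normal cell factors (default 0.3).
#' @return genes x cells numeric matrix.
#' @export
simulateNullGenes <- function(positions, nGenes = 100L,
                              noise = c("gaussian", "poisson"), seed = 0L,
                              meanExpr = 5, libSizeSd = 0.3) {
    noise <- match.arg(noise)
    n <- nrow(positions)
    set.seed(seed)
    X <- .noiseMatrix(nGenes, n, noise, meanExpr, libSizeSd,
                      matrix(0, nGenes, n))
    dimnames(X) <- list(sprintf("null%d", seq_len(nGenes)), rownames(positions))
    X
}

.standardize <- function(s) (s - mean(s)) / sd(s)

# smooth latent spatial field: standardized mixture of Gaussian bumps
.smoothField <- function(coords, nBumps = 3L) {
    diag <- .bboxDiag(coords)
    s <- rep(0, nrow(coords))
    for (b in seq_len(nBumps)) {
        ctr <- coords[sample.int(nrow(coords), 1L), 1:2]
        wid <- runif(1, 0.15, 0.35) * diag
        d2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2
        s <- s + sample(c(-1, 1), 1L) * exp(-d2 / (2 * wid^2))
    }
    .standardize(s)
}

#' Simulate spatially patterned genes with known truth
#'
#' Mean surfaces per kind -- \code{"gradient"}: linear in a random
#' direction; \code{"hotspot"}: Gaussian bump at a random center;
#' \code{"tiny_hotspot"}: exactly \code{spikeCells} mutually adjacent cells
#' spiked at \code{+spike} noise sd (the hotspot-artifact guard scenario;
#' \code{effect} is ignored); \code{"stripes"}: sinusoid of frequency
#' \code{freq}, with an anti-phase variant alternating phase by pi between
#' consecutive genes; \code{"two_blob"}: +/- \code{effect} split by a random
#' hyperplane. Surfaces (except the tiny hotspot) are standardized and
#' scaled by \code{effect}, so \code{effect} is the signal-to-noise ratio
#' under Gaussian sd-1 noise.
#'
#' @param positions positions data.frame from \code{\link{simulatePositions}}.
#' @param kind pattern kind (see above).
#' @param nGenes number of genes.
#' @param effect signal-to-noise scale (> 0; default 2).
#' @param noise \code{"gaussian"} or \code{"poisson"}.
#' @param seed integer seed.
#' @param freq stripe frequency (cycles across the bounding box; default 3).
#' @param antiPhase alternate stripe phase by pi between consecutive genes.
#' @param sharedPattern logical; when TRUE all genes share one random mean
#'   surface (a gene module expressing a common spatial pattern, differing
#'   only in noise), when FALSE (default) each gene draws its own surface.
#' @param theta optional fixed pattern axis in radians for the gradient,
#'   stripe and two-blob kinds (random per gene when NULL); lets callers
#'   construct spatially near-orthogonal pattern modules.
#' @param center optional fixed (x, y) hotspot center (random cell when
#'   NULL).
#' @param spike,spikeCells tiny-hotspot amplitude (in noise sd) and size.
#' @param meanExpr,libSizeSd Poisson noise parameters.
#' @return list with \code{expr} (genes x cells) and \code{truth}
#'   (data.frame of per-gene kind labels).
#' @export
simulatePatternGenes <- function(positions,
                                 kind = c("gradient", "hotspot",
                                          "tiny_hotspot", "stripes",
                                          "two_blob"),
                                 nGenes = 10L, effect = 2,
                                 noise = c("gaussian", "poisson"), seed = 0L,
                                 freq = 3, antiPhase = FALSE,
                                 sharedPattern = FALSE, theta = NULL,
                                 center = NULL, spike = 5,
                                 spikeCells = 3L,
                                 meanExpr = 5, libSizeSd = 0.3) {
    kind <- match.arg(kind)
    noise <- match.arg(noise)
    if (effect <= 0) stop("effect must be > 0")
    coords <- .asCoords(positions)
    n <- nrow(coords)
    set.seed(seed)
    sharedTheta <- runif(1, 0, pi)   # common stripe axis for anti-phase sets
    triples <- NULL
    if (kind == "tiny_hotspot") {
        if (spikeCells > 3L) stop("spikeCells must be <= 3")
        sw <- delaunayAdjacency(coords)
        e <- edgeList(sw)
        W <- weightMatrix(sw)
        # triangles: edge (i,j) plus a common neighbor
        triples <- lapply(seq_len(nGenes), function(g) {
            repeat {
                k <- sample.int(nrow(e), 1L)
                i <- e[k, 1]; j <- e[k, 2]
                common <- which(W[i, ] > 0 & W[j, ] > 0)
                if (length(common)) {
                    k2 <- common[sample.int(length(common), 1L)]
                    return(c(i, j, k2)[seq_len(spikeCells)])
                }
            }
        })
    }
    surf <- matrix(0, nGenes, n)
    for (g in seq_len(nGenes)) {
        if (sharedPattern && g > 1L && kind != "tiny_hotspot") {
            surf[g, ] <- surf[1L, ]
            next
        }
        surf[g, ] <- switch(kind,
            gradient = {
                th <- if (is.null(theta)) runif(1, 0, 2 * pi) else theta
                .standardize(coords[, 1] * cos(th) + coords[, 2] * sin(th))
            },
            hotspot = {
                ctr <- if (is.null(center)) coords[sample.int(n, 1L), 1:2]
                       else center
                wid <- 0.15 * .bboxDiag(coords)
                .standardize(exp(-((coords[, 1] - ctr[1])^2 +
                                   (coords[, 2] - ctr[2])^2) / (2 * wid^2)))
            },
            tiny_hotspot = rep(0, n),
            stripes = {
                th <- if (!is.null(theta)) theta
                      else if (antiPhase) sharedTheta else runif(1, 0, pi)
                ph <- if (antiPhase && g %% 2 == 0) pi else 0
                pr <- coords[, 1] * cos(th) + coords[, 2] * sin(th)
                pr <- (pr - min(pr)) / (max(pr) - min(pr))
                .standardize(sin(2 * pi * freq * pr + ph))
            },
            two_blob = {
                th <- if (is.null(theta)) runif(1, 0, 2 * pi) else theta
                pr <- coords[, 1] * cos(th) + coords[, 2] * sin(th)
                sign(pr - median(pr))
            })
    }
    X <- .noiseMatrix(nGenes, n, noise, meanExpr, libSizeSd, effect * surf)
    if (kind == "tiny_hotspot") {
        for (g in seq_len(nGenes)) X[g, triples[[g]]] <- X[g, triples[[g]]] + spike
    }
    dimnames(X) <- list(sprintf("%s%d", kind, seq_len(nGenes)),
                        rownames(coords))
    truth <- data.frame(gene = rownames(X), kind = kind,
                        stringsAsFactors = FALSE)
    if (kind == "tiny_hotspot")
        attr(truth, "spikedCells") <- lapply(triples, function(tr)
            rownames(coords)[tr])
    list(expr = X, truth = truth)
}

#' Simulate a two-cell-type communication scenario
#'
#' Cells are randomly (hence spatially interleaved) assigned to types A and
#' B. The planted receptor-ligand pair expresses one shared smooth latent
#' spatial field -- the receptor gene read out in A cells, the ligand gene
#' in B cells -- producing genuine inter-type spatial cross-correlation.
#' Null pairs are spatially unstructured i.i.d. genes, matching the
#' exchangeability assumption of the random-label permutation test.
#'
#' @param positions positions data.frame.
#' @param fracA fraction of type-A cells (default 0.5).
#' @param nPairs total receptor-ligand pairs (the first is the planted one
#'   when \code{planted}).
#' @param planted logical; plant a communicating pair (default TRUE).
#' @param effect signal-to-noise of the planted field (default 2).
#' @param seed integer seed.
#' @return list with \code{expr} (2*nPairs genes x cells), \code{types}
#'   (named character), \code{pairs} (receptor/ligand data.frame), and
#'   \code{truth} (planted pair or NULL).
#' @export
simulateCommunication <- function(positions, fracA = 0.5, nPairs = 50L,
                                  planted = TRUE, effect = 2, seed = 0L) {
    if (fracA <= 0 || fracA >= 1) stop("fracA must be in (0, 1)")
    coords <- .asCoords(positions)
    n <- nrow(coords)
    set.seed(seed)
    types <- setNames(sample(c("A", "B"), n, replace = TRUE,
                             prob = c(fracA, 1 - fracA)), rownames(coords))
    rec <- matrix(rnorm(nPairs * n), nPairs, n)
    lig <- matrix(rnorm(nPairs * n), nPairs, n)
    if (planted) {
        # shared latent field, read out type-specifically: the receptor gene
        # carries it only in A cells, the ligand gene only in B cells, so the
        # signal is directional by construction
        f <- .smoothField(coords)
        a <- types == "A"; b <- !a
        rec[1L, a] <- effect * f[a] + rnorm(sum(a))
        lig[1L, b] <- effect * f[b] + rnorm(sum(b))
    }
    expr <- rbind(rec, lig)
    dimnames(expr) <- list(c(sprintf("R%d", seq_len(nPairs)),
                             sprintf("L%d", seq_len(nPairs))),
                           rownames(coords))
    list(expr = expr, types = types,
         pairs = data.frame(receptor = sprintf("R%d", seq_len(nPairs)),
                            ligand = sprintf("L%d", seq_len(nPairs)),
                            stringsAsFactors = FALSE),
         truth = if (planted) c(receptor = "R1", ligand = "L1") else NULL)
}

#' Simulate transcriptionally identical, spatially distinct clusters
#'
#' All cells draw expression from one common distribution (i.i.d. standard
#' normal per gene), while the positions place them on two spatially
#' disconnected islands. Expression alone cannot separate the islands; the
#' island labels are returned as ground truth for spatially informed
#' clustering.
#'
#' @param positions a \code{"two_islands"} layout from
#'   \code{\link{simulatePositions}} (must carry an \code{island} column).
#' @param nGenes number of genes (default 10).
#' @param seed integer seed.
#' @return list with \code{expr} and the named factor \code{island}.
#' @export
simulateSplitClusters <- function(positions, nGenes = 10L, seed = 0L) {
    if (!"island" %in% colnames(positions))
        stop("positions must come from the 'two_islands' layout")
    n <- nrow(positions)
    set.seed(seed)
    expr <- matrix(rnorm(nGenes * n), nGenes, n,
                   dimnames = list(sprintf("gene%d", seq_len(nGenes)),
                                   rownames(positions)))
    list(expr = expr,
         island = setNames(factor(positions$island), rownames(positions)))
}
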