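test_that("the cross-correlation of a gene with itself is half its Moran's I", {
    pos <- simulatePositions(70, seed = 91)
    sw <- delaunayAdjacency(pos)
    set.seed(92)
    for (rep in 1:5) {
        x <- rnorm(70); names(x) <- rownames(pos)
        expect_equal(spatialCrossCor(x, x, sw), moransI(x, sw) / 2)
    }
})

test_that("identical two-blob genes give SCI = 1/2 and symmetry holds", {
    pos <- simulatePositions(80, "two_islands", seed = 93)
    sw <- suppressMessages(delaunayAdjacency(pos, prune = "auto"))
    x <- setNames(ifelse(pos$island == "island1", 1, -1), rownames(pos))
    expect_equal(spatialCrossCor(x, x, sw), 0.5)
    y <- simulateNullGenes(pos, 1, seed = 94)[1, ]
    expect_equal(spatialCrossCor(x, y, sw), spatialCrossCor(y, x, sw))
    expect_error(spatialCrossCor(x, rep(1, 80), sw), "constant")
})

test_that("the matrix route equals looping over pairs", {
    pos <- simulatePositions(60, seed = 95)
    sw <- delaunayAdjacency(pos)
    X <- simulateNullGenes(pos, 10, seed = 96)
    sci <- spatialCrossCorMatrix(X, sw)
    expect_true(isSymmetric(sci, tol = 1e-12))
    for (g in c(1, 4, 7)) for (h in c(2, 9)) {
        expect_equal(sci[g, h], spatialCrossCor(X[g, ], X[h, ], sw),
                     tolerance = 1e-12)
    }
    mt <- moranTest(X, sw)
    expect_equal(unname(diag(sci)), unname(mt$observed) / 2)
    # permuting gene order permutes the matrix consistently
    perm <- sample(10)
    sci2 <- spatialCrossCorMatrix(X[perm, ], sw)
    expect_equal(sci2, sci[perm, perm])
})

test_that("three planted pattern modules are recovered as three groups", {
    pos <- simulatePositions(200, seed = 97)
    sw <- delaunayAdjacency(pos, prune = "auto")
    X <- rbind(
        simulatePatternGenes(pos, "gradient", nGenes = 10, effect = 2,
                             seed = 98, sharedPattern = TRUE, theta = 0)$expr,
        simulatePatternGenes(pos, "hotspot", nGenes = 10, effect = 2,
                             seed = 99, sharedPattern = TRUE,
                             center = c(0.5, 0.5))$expr,
        simulatePatternGenes(pos, "stripes", nGenes = 10, effect = 2,
                             seed = 100, sharedPattern = TRUE,
                             theta = pi / 2)$expr)
    truth <- rep(1:3, each = 10)
    gp <- groupPatterns(spatialCrossCorMatrix(X, sw))
    expect_equal(gp$k, 3L)
    expect_gte(mclust::adjustedRandIndex(gp$pattern, truth), 0.9)
    # invariant to gene input order
    set.seed(101)
    perm <- sample(nrow(X))
    gp2 <- groupPatterns(spatialCrossCorMatrix(X[perm, ], sw))
    expect_equal(mclust::adjustedRandIndex(gp$pattern[rownames(X)],
                                           gp2$pattern[rownames(X)]), 1)
    # exact duplicates always co-cluster
    Xd <- rbind(X, X[c(1, 11, 21), ] )
    rownames(Xd) <- c(rownames(X), "d1", "d2", "d3")
    gpd <- groupPatterns(spatialCrossCorMatrix(Xd, sw))
    expect_equal(unname(gpd$pattern["d1"]), unname(gpd$pattern["gradient1"]))
    expect_equal(unname(gpd$pattern["d2"]), unname(gpd$pattern["hotspot1"]))
})

test_that("a block SCI matrix with two positive blocks cuts into two patterns", {
    g <- 16
    sci <- matrix(0, g, g, dimnames = list(sprintf("g%d", 1:g),
                                           sprintf("g%d", 1:g)))
    set.seed(102)
    sci[1:8, 1:8] <- 0.4 + matrix(runif(64, -0.02, 0.02), 8)
    sci[9:16, 9:16] <- 0.4 + matrix(runif(64, -0.02, 0.02), 8)
    sci[1:8, 9:16] <- matrix(runif(64, -0.02, 0.02), 8)
    sci <- (sci + t(sci)) / 2
    diag(sci) <- 0.45
    gp <- groupPatterns(sci)
    expect_equal(gp$k, 2L)
    expect_equal(length(unique(gp$pattern[1:8])), 1L)
    expect_equal(length(unique(gp$pattern[9:16])), 1L)
    # too few genes: single pattern with a warning
    expect_warning(one <- groupPatterns(sci[1:3, 1:3]), "minPatternSize")
    expect_equal(unname(one$pattern), rep(1L, 3))
})

test_that("pattern summaries are Z-scored averages with mean zero", {
    pos <- simulatePositions(50, seed = 103)
    X <- simulatePatternGenes(pos, "gradient", nGenes = 4, seed = 104,
                              sharedPattern = TRUE)$expr
    pat <- setNames(c(1L, 1L, 2L, 0L), rownames(X))
    sm <- summarizePatterns(X, pat)
    expect_equal(colnames(sm), c("pattern1", "pattern2"))
    z3 <- (X[3, ] - mean(X[3, ])) / sd(X[3, ])
    expect_equal(unname(sm[, "pattern2"]), unname(z3))
    expect_equal(unname(colMeans(sm)), c(0, 0), tolerance = 1e-12)
    # duplicated gene changes nothing
    X2 <- rbind(X[3, , drop = FALSE], X[3, , drop = FALSE])
    rownames(X2) <- c("a", "b")
    sm2 <- summarizePatterns(X2, c(a = 1L, b = 1L))
    expect_equal(unname(sm2[, 1]), unname(z3))
    Xc <- rbind(X, flat = rep(1, ncol(X)))
    expect_error(summarizePatterns(Xc, c(pat, flat = 1L)), "Z-score")
})

test_that("anti-phase stripe summaries are approximate negatives", {
    pos <- simulatePositions(200, seed = 105)
    sw <- delaunayAdjacency(pos, prune = "auto")
    sim <- simulatePatternGenes(pos, "stripes", nGenes = 10, effect = 3,
                                seed = 106, antiPhase = TRUE)
    even <- sim$expr[seq(2, 10, 2), ]
    odd <- sim$expr[seq(1, 9, 2), ]
    sOdd <- summarizePatterns(odd, setNames(rep(1L, 5), rownames(odd)))
    sEven <- summarizePatterns(even, setNames(rep(1L, 5), rownames(even)))
    expect_lt(cor(sOdd[, 1], sEven[, 1]), -0.7)
})

test_that("grid interpolation reproduces data and linear fields", {
    co <- rbind(as.matrix(expand.grid(c(0, 1), c(0, 1))),
                randomCells(40, 2, seed = 107))
    dimnames(co) <- list(sprintf("c%d", seq_len(nrow(co))), c("x", "y"))
    # constant field stays constant inside the hull
    gC <- interpolatePattern(co, rep(2.5, nrow(co)), resolution = 21)
    expect_equal(unname(gC$z[!is.na(gC$z)]),
                 rep(2.5, sum(!is.na(gC$z))), tolerance = 1e-8)
    # bounding-box corners are data points and grid nodes: exact reproduction
    gD <- interpolatePattern(co, co[, 1] + 2 * co[, 2], resolution = 11)
    expect_equal(gD$z[1, 1], 0, tolerance = 1e-6)
    expect_equal(gD$z[11, 11], 3, tolerance = 1e-6)
    # linear field recovered inside the hull
    lin <- interpolatePattern(co, co[, 1], resolution = 21)
    truth <- outer(gC$x, rep(1, 21))
    err <- abs(lin$z - truth)
    expect_lt(max(err, na.rm = TRUE), 1e-3)
    expect_error(interpolatePattern(cbind(co, 1), co[, 1]), "2D")
    expect_error(interpolatePattern(co, co[, 1], resolution = 1), ">= 2")
})
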