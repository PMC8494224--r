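test_that("uniform layouts triangulate to the planar mean degree of about six", {
    pos <- simulatePositions(1000, seed = 141)
    sw <- delaunayAdjacency(pos)
    deg <- Matrix::rowSums(weightMatrix(sw))
    # Euler: mean degree 6 - O(boundary/N); generous 3-SE-style band
    expect_lt(abs(mean(deg) - 6), 3 * sd(deg) / sqrt(1000) + 12 / sqrt(1000))
})

test_that("generators are pure functions of their seed", {
    for (lay in c("uniform", "density_gradient", "distorted",
                  "multi_section", "two_islands")) {
        a <- simulatePositions(50, lay, seed = 142)
        b <- simulatePositions(50, lay, seed = 142)
        expect_identical(a, b)
    }
    pos <- simulatePositions(50, seed = 143)
    expect_identical(simulateNullGenes(pos, 5, seed = 1),
                     simulateNullGenes(pos, 5, seed = 1))
    expect_identical(simulatePatternGenes(pos, "stripes", seed = 2),
                     simulatePatternGenes(pos, "stripes", seed = 2))
    expect_identical(simulateCommunication(pos, nPairs = 3, seed = 3),
                     simulateCommunication(pos, nPairs = 3, seed = 3))
    posI <- simulatePositions(40, "two_islands", seed = 144)
    expect_identical(simulateSplitClusters(posI, seed = 4),
                     simulateSplitClusters(posI, seed = 4))
})

test_that("the identity warp is the uniform layout", {
    u <- simulatePositions(60, "uniform", seed = 145)
    w <- simulatePositions(60, "distorted", gammaWarp = 1, seed = 145)
    expect_equal(u$x, w$x)
    expect_equal(u$y, w$y)
})

test_that("density layouts concentrate mass where the intensity says", {
    g <- simulatePositions(4000, "density_gradient", gradientRate = 2,
                           seed = 146)
    expect_gt(mean(g$x > 0.5), 0.6)   # exp(2x) intensity skews right
    d <- simulatePositions(4000, "distorted", gammaWarp = 2, seed = 147)
    expect_gt(mean(d$x < 0.5), 0.6)   # x^2 compresses toward zero
})

test_that("null genes reproduce the analytic null mean of Moran's I", {
    pos <- simulatePositions(120, seed = 148)
    sw <- delaunayAdjacency(pos)
    X <- simulateNullGenes(pos, 400, seed = 149)
    mt <- moranTest(X, sw)
    se <- sd(mt$observed) / sqrt(400)
    expect_lt(abs(mean(mt$observed) - (-1 / 119)), 3 * se)
})

test_that("pattern archetypes carry their advertised structure", {
    pos <- simulatePositions(150, seed = 150)
    sw <- delaunayAdjacency(pos, prune = "auto")
    posBig <- simulatePositions(400, seed = 149)
    swBig <- delaunayAdjacency(posBig, prune = "auto")
    blob <- simulatePatternGenes(posBig, "two_blob", nGenes = 1, effect = 50,
                                 seed = 151)$expr[1, ]
    # hyperplane split: only the thin boundary keeps I below its limit of 1
    expect_gt(moransI(blob, swBig), 0.85)
    tiny <- simulatePatternGenes(pos, "tiny_hotspot", nGenes = 3, seed = 152)
    W <- as.matrix(weightMatrix(delaunayAdjacency(pos)))
    spikedList <- attr(tiny$truth, "spikedCells")
    for (g in 1:3) {
        spiked <- spikedList[[g]]
        expect_equal(length(spiked), 3L)
        expect_true(all(W[spiked, spiked][upper.tri(diag(3))] == 1))
        expect_gt(min(tiny$expr[g, spiked]), 1.5)  # +5 sd spikes stand out
    }
    st <- simulatePatternGenes(pos, "stripes", nGenes = 2, effect = 3,
                               seed = 153, antiPhase = TRUE)$expr
    expect_lt(cor(st[1, ], st[2, ]), -0.5)
    mt <- moranTest(st, sw)
    expect_true(all(mt$p.value < 0.01))  # each phase individually significant
    expect_error(simulatePatternGenes(pos, "gradient", effect = 0), "effect")
})

test_that("multi-section layouts align across sections", {
    pos <- simulatePositions(100, "multi_section", nSections = 2,
                             sectionJitter = 0.001, seed = 154)
    expect_setequal(unique(pos$section), c("s1", "s2"))
    swx <- crossSectionAdjacency(pos, pos$section, k = 1)
    # tiny jitter: nearly every cell pairs with its own copy
    expect_gt(sum(weightMatrix(swx)) / 2, 45)
})

test_that("split-cluster fixtures are spatially disjoint but mixed in expression", {
    pos <- simulatePositions(100, "two_islands", seed = 155)
    sw <- suppressMessages(delaunayAdjacency(pos, prune = "auto"))
    sim <- simulateSplitClusters(pos, nGenes = 10, seed = 156)
    d <- geodesicDistances(sw)
    i1 <- names(sim$island)[sim$island == "island1"]
    i2 <- names(sim$island)[sim$island == "island2"]
    expect_true(all(is.infinite(d[i1, i2])))
    g <- knnExpressionGraph(sim$expr, nPcs = 5, k = 10)
    ends <- igraph::ends(g, igraph::E(g))
    cross <- xor(ends[, 1] %in% i1, ends[, 2] %in% i1)
    expect_gt(mean(cross), 0.3)  # expression graph ignores the islands
})

test_that("communication fixtures plant exactly one exchangeable violation", {
    pos <- simulatePositions(200, seed = 157)
    simP <- simulateCommunication(pos, nPairs = 5, planted = TRUE, seed = 158)
    expect_identical(unname(simP$truth), c("R1", "L1"))
    expect_identical(dim(simP$expr), c(10L, 200L))
    simN <- simulateCommunication(pos, nPairs = 5, planted = FALSE, seed = 158)
    expect_null(simN$truth)
    expect_error(simulateCommunication(pos, fracA = 1), "fracA")
})
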