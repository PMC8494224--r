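test_that("a triangle is its own triangulation", {
    sw <- delaunayAdjacency(matrix(c(0, 0, 1, 0, 0.5, 1), 3, 2, byrow = TRUE))
    expect_equal(nrow(edgeList(sw)), 3L)
    expect_equal(sum(weightMatrix(sw)), 6)
})

test_that("the long pair of a flat quadrilateral is not a Delaunay edge", {
    pts <- matrix(c(0, 0, 10, 0, 5, 1, 5, -1), 4, 2, byrow = TRUE)
    rownames(pts) <- c("a", "b", "c", "d")
    sw <- delaunayAdjacency(pts)
    W <- weightMatrix(sw)
    expect_equal(nrow(edgeList(sw)), 5L)
    expect_equal(W["a", "b"], 0)
})

test_that("Delaunay adjacency matches the empty-circumcircle oracle (2D and 3D)", {
    set.seed(101)
    for (rep in 1:8) {
        c2 <- randomCells(sample(8:25, 1), 2)
        got <- as.matrix(weightMatrix(delaunayAdjacency(c2))) > 0
        expect_identical(unname(got), oracleDelaunayEdges(c2))
        c3 <- randomCells(sample(8:13, 1), 3)
        got3 <- as.matrix(weightMatrix(delaunayAdjacency(c3))) > 0
        expect_identical(unname(got3), oracleDelaunayEdges(c3))
    }
})

test_that("adjacency is symmetric, binary, hollow, and rigid-motion invariant", {
    set.seed(7)
    for (rep in 1:5) {
        co <- randomCells(30, 2)
        W <- weightMatrix(delaunayAdjacency(co))
        expect_true(Matrix::isSymmetric(W))
        expect_true(all(W@x %in% c(0, 1)))
        expect_true(all(Matrix::diag(W) == 0))
        th <- runif(1, 0, 2 * pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        co2 <- co %*% R + 5
        rownames(co2) <- rownames(co)
        expect_equal(as.matrix(weightMatrix(delaunayAdjacency(co2))),
                     as.matrix(W))
    }
})

test_that("degenerate inputs are rejected with informative errors", {
    line <- cbind(1:5, 2 * (1:5))
    expect_error(delaunayAdjacency(line), "collinear")
    plane <- cbind(randomCells(10, 2, seed = 1), 0)
    expect_error(delaunayAdjacency(plane), "coplanar")
    expect_error(delaunayAdjacency(matrix(c(0, 0, 1, 1), 2, 2)),
                 "at least 3 points")
    dup <- rbind(randomCells(10, 2, seed = 2), c(0.5, 0.5), c(0.5, 0.5))
    rownames(dup) <- sprintf("c%d", 1:12)
    expect_error(delaunayAdjacency(dup), "duplicate")
    expect_s4_class(delaunayAdjacency(dup, jitter = TRUE), "SpatialWeights")
})

test_that("jitter is deterministic and leaves the RNG stream untouched", {
    dup <- rbind(randomCells(12, 2, seed = 3), c(0.2, 0.2), c(0.2, 0.2))
    rownames(dup) <- sprintf("c%d", 1:14)
    a <- delaunayAdjacency(dup, jitter = TRUE, jitterSeed = 9L)
    set.seed(42)
    b <- delaunayAdjacency(dup, jitter = TRUE, jitterSeed = 9L)
    after <- runif(3)
    expect_identical(as.matrix(weightMatrix(a)), as.matrix(weightMatrix(b)))
    set.seed(42)
    expect_identical(after, runif(3))  # jitter drew from its own stream
})

test_that("pruning removes long edges monotonically and records isolation", {
    co <- randomCells(40, 2, seed = 11)
    sw <- delaunayAdjacency(co)
    expect_equal(as.matrix(weightMatrix(pruneLongEdges(sw, Inf))),
                 as.matrix(weightMatrix(sw)))
    pr <- pruneLongEdges(sw, maxDist = "auto")
    expect_true(all(weightMatrix(pr) <= weightMatrix(sw)))
    expect_true(Matrix::isSymmetric(weightMatrix(pr)))
    e <- edgeList(sw)
    len <- sqrt(rowSums((co[e[, 1], ] - co[e[, 2], ])^2))
    short <- min(len)
    expect_error(pruneLongEdges(sw, maxDist = -1), "positive")
    expect_error(pruneLongEdges(sw, maxDist = short / 2), "every edge")
    # a specific too-long edge disappears
    twoPts <- delaunayAdjacency(rbind(randomCells(20, 2, seed = 12) * 0.2,
                                      far = c(5, 5)))
    prn <- suppressMessages(pruneLongEdges(twoPts, maxDist = 4))
    expect_equal(sum(weightMatrix(prn)["far", ]), 0)
    expect_true("far" %in% prn@meta$isolated)
})

test_that("inter-type restriction matches an edge-list scan", {
    co <- randomCells(60, 2, seed = 21)
    sw <- delaunayAdjacency(co)
    set.seed(22)
    ty <- setNames(sample(c("A", "B"), 60, TRUE), rownames(co))
    itw <- interTypeAdjacency(sw, ty, "A", "B")
    e <- edgeList(sw)
    ids <- cellIds(sw)
    crossEdges <- sum(ty[ids[e[, 1]]] != ty[ids[e[, 2]]])
    expect_equal(sum(weightMatrix(itw)), crossEdges)
    # typeA == typeB == everything recovers W itself
    all1 <- setNames(rep("T", 60), rownames(co))
    itwAll <- interTypeAdjacency(sw, all1, "T", "T")
    expect_equal(as.matrix(weightMatrix(itwAll)),
                 as.matrix(weightMatrix(sw)))
    expect_error(interTypeAdjacency(sw, ty, "A", "nope"), "unknown")
})

test_that("distance-pruned type islands yield zero inter-type edges", {
    pos <- simulatePositions(60, "two_islands", seed = 23)
    sw <- suppressMessages(delaunayAdjacency(pos, prune = "auto"))
    ty <- setNames(ifelse(pos$island == "island1", "A", "B"), rownames(pos))
    expect_warning(itw <- interTypeAdjacency(sw, ty, "A", "B"),
                   "no inter-type edges")
    expect_equal(sum(weightMatrix(itw)), 0)
})

test_that("cross-section MNN pairing matches brute force and is mutual-safe", {
    # identical grids, k = 1: perfect one-to-one pairing
    g <- expand.grid(x = 1:4, y = 1:4)
    pos <- data.frame(x = c(g$x, g$x), y = c(g$y, g$y),
                      section = rep(c("s1", "s2"), each = 16))
    rownames(pos) <- sprintf("c%d", 1:32)
    swx <- crossSectionAdjacency(pos, pos$section, k = 1)
    expect_equal(sum(weightMatrix(swx)) / 2, 16)
    expect_equal(unname(Matrix::rowSums(weightMatrix(swx))), rep(1, 32))
    # random two-section layout vs oracle
    set.seed(31)
    ca <- randomCells(20, 2); cb <- randomCells(25, 2)
    rownames(cb) <- sprintf("d%d", 1:25)
    pos2 <- data.frame(x = c(ca[, 1], cb[, 1]), y = c(ca[, 2], cb[, 2]),
                       section = rep(c("s1", "s2"), c(20, 25)))
    rownames(pos2) <- c(rownames(ca), rownames(cb))
    swx2 <- crossSectionAdjacency(pos2, pos2$section, k = 3)
    expect_equal(unname(as.matrix(weightMatrix(swx2))[1:20, 21:45] > 0),
                 unname(oracleMutualKnn(ca, cb, 3)))
    expect_error(crossSectionAdjacency(pos2, rep("s1", 45), k = 3),
                 "two sections")
})

test_that("geodesic distances are hop counts with Inf across components", {
    W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 1
    sw <- SpatialWeights(W)
    d <- geodesicDistances(sw)
    expect_equal(unname(diag(d)), c(0, 0, 0))
    expect_equal(d["cell1", "cell3"], 2)
    pos <- simulatePositions(60, "two_islands", seed = 41)
    sw2 <- suppressMessages(delaunayAdjacency(pos, prune = "auto"))
    d2 <- geodesicDistances(sw2)
    i1 <- rownames(pos)[pos$island == "island1"]
    i2 <- rownames(pos)[pos$island == "island2"]
    expect_true(all(is.infinite(d2[i1, i2])))
    # distance 1 exactly on the support; triangle inequality on a sample
    W2 <- as.matrix(weightMatrix(sw2))
    expect_true(all(d2[W2 == 1] == 1))
    set.seed(42)
    for (r in 1:200) {
        ijk <- sample(i1, 3)
        expect_lte(d2[ijk[1], ijk[3]], d2[ijk[1], ijk[2]] + d2[ijk[2], ijk[3]])
    }
})
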