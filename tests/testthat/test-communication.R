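commFixture <- function(n = 300, nPairs = 10, seed = 111, effect = 2) {
    pos <- simulatePositions(n, seed = seed)
    sw <- delaunayAdjacency(pos, prune = "auto")
    sim <- simulateCommunication(pos, nPairs = nPairs, planted = TRUE,
                                 effect = effect, seed = seed + 1)
    list(pos = pos, sw = sw, sim = sim)
}

test_that("complementary gradients give positive iSCI, anti-complementary negative", {
    pos <- simulatePositions(300, seed = 112)
    sw <- delaunayAdjacency(pos, prune = "auto")
    set.seed(113)
    types <- setNames(sample(c("A", "B"), 300, TRUE), rownames(pos))
    itw <- interTypeAdjacency(sw, types, "A", "B")
    f <- pos$x  # shared axis
    names(f) <- rownames(pos)
    a <- names(types)[types == "A"]; b <- names(types)[types == "B"]
    xa <- f[a] + rnorm(length(a), sd = 0.1)
    yb <- f[b] + rnorm(length(b), sd = 0.1)
    expect_gt(interTypeCrossCor(xa, yb, itw), 0.2)
    expect_lt(interTypeCrossCor(xa, max(f) - f[b] + rnorm(length(b), 0.1), itw),
              -0.2)
    # invariant to independent positive affine transforms of the two sides
    expect_equal(interTypeCrossCor(3 * xa + 5, yb, itw),
                 interTypeCrossCor(xa, yb, itw))
    expect_error(interTypeCrossCor(rep(1, length(a)), yb, itw), "constant")
})

test_that("shuffled ligand values center the permutation null near its mean", {
    fx <- commFixture()
    types <- fx$sim$types
    itw <- interTypeAdjacency(fx$sw, types, "A", "B")
    a <- names(types)[types == "A"]; b <- names(types)[types == "B"]
    xa <- fx$sim$expr["R1", a]; yb <- fx$sim$expr["L1", b]
    obs <- interTypeCrossCor(xa, yb, itw)
    set.seed(114)
    st <- replicate(3000, interTypeCrossCor(xa, sample(unname(yb)), itw))
    expect_lt(abs(mean(st)), 4 * sd(st) / sqrt(3000) + 0.01)
    expect_gt(obs, quantile(st, 0.999))  # planted pair is far in the tail
})

test_that("the adaptive ladder escalates exactly when the estimate saturates", {
    st <- function(nPerm, seed) { set.seed(seed); rnorm(nPerm) }
    # observed below the null median: no escalation
    r <- adaptivePermutationTest(-1, st, seed = 1)
    expect_equal(r$nPerm, 100L)
    expect_gt(r$p.value, 0.5)
    # observed beyond everything: escalate to the cap
    r2 <- adaptivePermutationTest(50, st, seed = 1)
    expect_equal(r2$nPerm, 10000L)
    expect_equal(r2$p.value, 1 / 10001)
    expect_gt(r2$p.value, 0)  # (r+1)/(n+1) never returns zero
    expect_error(adaptivePermutationTest(0, st, basePerms = 10), ">= 20")
})

test_that("screens are reproducible and rank a planted pair first", {
    fx <- commFixture(nPairs = 20)
    res <- screenPairs(fx$sim$expr, fx$sim$types, fx$sw, fx$sim$pairs,
                       "A", "B", minCells = 10, seed = 115)
    expect_equal(res$receptor[1], "R1")
    expect_lt(res$p.adj[1], 0.05)
    expect_true(all(res$p.value > 0))
    expect_true(all(res$n_perm %in% c(100L, 1000L, 10000L)))
    res2 <- screenPairs(fx$sim$expr, fx$sim$types, fx$sw, fx$sim$pairs,
                        "A", "B", minCells = 10, seed = 115)
    expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("direction is explicit: the planted signal shows only receptor-in-A", {
    fx <- commFixture(n = 400, nPairs = 8)
    ab <- screenPairs(fx$sim$expr, fx$sim$types, fx$sw, fx$sim$pairs,
                      "A", "B", direction = "AB", minCells = 10, seed = 116)
    ba <- screenPairs(fx$sim$expr, fx$sim$types, fx$sw, fx$sim$pairs,
                      "A", "B", direction = "BA", minCells = 10, seed = 117)
    expect_lt(ab$p.adj[ab$receptor == "R1"], 0.05)
    expect_gt(ba$p.value[ba$receptor == "R1"], 0.05)
})

test_that("degenerate screens fail loudly or emptily as appropriate", {
    fx <- commFixture(nPairs = 4)
    # no inter-type edges: disjoint pruned islands
    pos <- simulatePositions(60, "two_islands", seed = 118)
    swI <- suppressMessages(delaunayAdjacency(pos, prune = "auto"))
    tyI <- setNames(ifelse(pos$island == "island1", "A", "B"), rownames(pos))
    ex <- matrix(rnorm(2 * 60), 2, 60,
                 dimnames = list(c("R1", "L1"), rownames(pos)))
    expect_error(
        suppressWarnings(screenPairs(ex, tyI, swI,
                                     data.frame(receptor = "R1", ligand = "L1"),
                                     "A", "B", minCells = 0, seed = 1)),
        "no inter-type edges")
    # nothing survives an impossible detection filter
    expect_warning(
        empty <- screenPairs(fx$sim$expr, fx$sim$types, fx$sw, fx$sim$pairs,
                             "A", "B", minCells = 1000, seed = 1),
        "no receptor-ligand pair")
    expect_equal(nrow(empty), 0L)
    dupPairs <- rbind(fx$sim$pairs, fx$sim$pairs[1, ])
    expect_error(screenPairs(fx$sim$expr, fx$sim$types, fx$sw, dupPairs,
                             "A", "B", seed = 1), "duplicate")
})

test_that("null permutation p-values are super-uniform at usual levels", {
    pos <- simulatePositions(250, seed = 119)
    sw <- delaunayAdjacency(pos, prune = "auto")
    sim <- simulateCommunication(pos, nPairs = 60, planted = FALSE,
                                 seed = 120)
    res <- screenPairs(sim$expr, sim$types, sw, sim$pairs, "A", "B",
                       minCells = 10, seed = 121)
    expect_equal(nrow(res), 60L)
    for (a in c(0.05, 0.1, 0.2)) {
        se <- sqrt(a * (1 - a) / 60)
        expect_lte(mean(res$p.value < a), a + 3 * se)
    }
})
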