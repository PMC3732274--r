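test_that("tree simulation is seeded, binary and positive-length", {
    t1 <- simTree(10, seed = 5)
    t2 <- simTree(10, seed = 5)
    expect_identical(ape::write.tree(t1), ape::write.tree(t2))
    expect_length(treeSplits(t1), 7L)        # n - 3 internal splits
    expect_gt(sum(t1$edge.length), 0)
    expect_error(simTree(3), "4 leaves")
})

test_that("alignment simulation is seeded and collapses at zero rate", {
    tr <- simTree(6, seed = 2)
    p <- simulationParams(length = 120, seed = 9)
    a1 <- simAlignment(tr, p); a2 <- simAlignment(tr, p)
    expect_identical(alignmentMatrix(a1), alignmentMatrix(a2))
    a0 <- simAlignment(tr, simulationParams(length = 60, rateMultiplier = 0,
                                            seed = 4))
    expect_equal(classifySites(a0)$variable, 0L)
    expect_error(simulationParams(baseFreq = c(0.5, 0.5, 0.2, 0.2)), "sum to 1")
})

test_that("simulated composition converges to the stationary frequencies", {
    tr <- ape::read.tree(text = "(A:0.02,B:0.02);")
    pi0 <- c(0.1, 0.2, 0.3, 0.4)
    aln <- simAlignment(tr, simulationParams(baseFreq = pi0, length = 20000,
                                             seed = 11))
    counts <- colSums(baseComposition(aln)$counts)
    gof <- suppressWarnings(chisq.test(counts, p = pi0))
    expect_gt(gof$p.value, 1e-4)
})

test_that("JC simulation matches the closed-form p-distance at moderate depth", {
    d <- 0.5
    tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", d / 2, d / 2))
    aln <- simAlignment(tr, simulationParams(alpha = Inf, length = 20000,
                                             seed = 23))
    expected <- 0.75 * (1 - exp(-4 * d / 3))
    p_hat <- pDistanceMatrix(aln)$d["A", "B"]
    expect_equal(p_hat, expected, tolerance = 0.03)
})

test_that("tree-sample generation reproduces the true tree at zero moves", {
    tr <- simTree(8, seed = 6)
    s1 <- simTreeSample(tr, 15, nniMoves = 0, seed = 7)
    s2 <- simTreeSample(tr, 15, nniMoves = 0, seed = 8)
    expect_equal(asdsf(list(s1, s2))$asdsf, 0)
    for (t in unclass(sampleTrees(s1)))
        expect_identical(treeSplits(t), treeSplits(tr))
})

test_that("rogue injection preserves the taxon set and is recovered", {
    tr <- simTree(12, seed = 10)
    s <- simTreeSample(tr, 300, nniMoves = 0, rogues = "t4", seed = 12)
    expect_equal(taxa(s), sort(tr$tip.label))
    rep <- findRogues(s, maxDropsetSize = 1)
    expect_true("t4" %in% unlist(rogueDropsets(rep)))
})

test_that("mean consensus resolution decreases with NNI perturbation", {
    set.seed(61)
    res_at <- function(moves, seeds) {
        mean(vapply(seeds, function(sd) {
            tr <- simTree(10, seed = sd)
            s <- simTreeSample(tr, 20, nniMoves = moves, seed = sd + 1000)
            resolutionPercent(majorityConsensus(s))
        }, 0))
    }
    seeds <- 1:20
    r <- vapply(c(0, 1, 3, 10), res_at, 0, seeds = seeds)
    expect_equal(r[1], 100)
    expect_true(all(diff(r) <= 0))
    expect_lt(r[4], r[1])
})

test_that("asdsf grows with NNI discordance between samples", {
    seeds <- 1:10
    asdsf_at <- function(moves) {
        mean(vapply(seeds, function(sd) {
            tr <- simTree(10, seed = sd)
            s1 <- simTreeSample(tr, 25, nniMoves = moves, seed = sd + 100)
            s2 <- simTreeSample(tr, 25, nniMoves = moves, seed = sd + 200)
            asdsf(list(s1, s2))$asdsf
        }, 0))
    }
    expect_lt(asdsf_at(1), asdsf_at(10))
})

test_that("presence simulation hits the target coverage in expectation", {
    pm1 <- simPresenceMatrix(10, 4, 1.0, seed = 3)
    expect_true(all(presenceValues(pm1)))
    pm2 <- simPresenceMatrix(137, 7, 0.84, seed = 4)
    pm2b <- simPresenceMatrix(137, 7, 0.84, seed = 4)
    expect_identical(presenceValues(pm2), presenceValues(pm2b))
    cov <- mean(vapply(1:30, function(s)
        mean(presenceValues(simPresenceMatrix(137, 7, 0.84, seed = s))), 0))
    expect_equal(cov, 0.84, tolerance = 0.01)
})
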