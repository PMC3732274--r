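test_that("split extraction yields exactly the internal-edge bipartitions", {
    expect_identical(treeSplits(tr4_star), list())
    expect_identical(treeSplits(tr4_ab), list(c("C", "D")))
    set.seed(3)
    for (n in c(5, 8, 13, 20)) {
        tr <- ape::rtree(n)
        sp <- treeSplits(tr)
        expect_length(sp, n - 3L)
        expect_length(unique(vapply(sp, paste, "", collapse = "|")), n - 3L)
        small <- sort(tr$tip.label)[1L]
        expect_false(any(vapply(sp, function(s) small %in% s, TRUE)))
    }
    ## rooted input is unrooted first: same splits either way
    tr <- ape::rtree(8, rooted = TRUE)
    expect_identical(treeSplits(tr), treeSplits(ape::unroot(tr)))
    dup <- ape::read.tree(text = "((A,A),(C,D));")
    expect_error(treeSplits(dup), "duplicate")
})

test_that("split frequencies count tree fractions with zero for absences", {
    sft <- splitFrequencyTable(list(a = rep_sample(tr4_ab, 10),
                                    b = rep_sample(tr4_ab, 10)))
    expect_equal(unname(apply(splitFrequencies(sft), 1, sd)), 0)

    sft2 <- splitFrequencyTable(list(a = rep_sample(tr4_ab, 10),
                                     b = rep_sample(tr4_ac, 10)))
    f <- splitFrequencies(sft2)
    expect_equal(sort(unname(f[, "a"])), c(0, 1))
    expect_equal(unname(apply(f, 1, sd)), rep(1 / sqrt(2), 2),
                 tolerance = 1e-12)

    sft3 <- splitFrequencyTable(mixed_sample(list(tr4_ab, tr4_star), c(3, 1)))
    expect_equal(unname(splitFrequencies(sft3)[1, 1]), 0.75)

    t5 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
    expect_error(splitFrequencyTable(list(rep_sample(tr4_ab, 2),
                                          rep_sample(t5, 2))),
                 "restrict")
})

test_that("split frequencies match the prop.part oracle", {
    set.seed(17)
    tr <- ape::rtree(10)
    sample <- simTreeSample(tr, 40, nniMoves = 2, seed = 99)
    f <- splitFrequencies(splitFrequencyTable(sample))[, 1]
    ## prop.part counts clades of rooted trees; unroot first (a rooted tree
    ## lists the split at the root twice) and aggregate a clade with its
    ## complement (basal-node placement differs across trees) by canonical
    ## side before comparing.
    un <- lapply(unclass(sampleTrees(sample)), ape::unroot)
    class(un) <- "multiPhylo"
    pp <- ape::prop.part(un)
    labs <- attr(pp, "labels")
    taxa_all <- sort(labs)
    oracle <- numeric(0)
    for (k in seq_along(pp)) {
        side <- sort(labs[pp[[k]]])
        if (length(side) < 2L || length(side) > length(labs) - 2L) next
        if (taxa_all[1L] %in% side) side <- setdiff(taxa_all, side)
        key <- paste(sort(side), collapse = "|")
        oracle[key] <- (if (key %in% names(oracle)) oracle[key] else 0) +
            attr(pp, "number")[k] / sampleSize(sample)
    }
    expect_setequal(names(oracle), names(f))
    expect_equal(f[names(oracle)], oracle)
})

test_that("asdsf matches hand oracles and is permutation invariant", {
    s_ab <- rep_sample(tr4_ab, 10); s_ac <- rep_sample(tr4_ac, 10)
    expect_equal(asdsf(list(s_ab, rep_sample(tr4_ab, 7)))$asdsf, 0)
    res <- asdsf(list(s_ab, s_ac))
    expect_equal(res$asdsf, sqrt(0.5), tolerance = 1e-9)
    expect_equal(res$n_splits_included, 2L)
    ## three samples, single included split at (1.0, 1.0, 0.4)
    s_mix <- mixed_sample(list(tr4_ab, tr4_star), c(4, 6))
    res3 <- asdsf(list(s_ab, rep_sample(tr4_ab, 5), s_mix))
    expect_equal(res3$asdsf, sd(c(1, 1, 0.4)), tolerance = 1e-12)
    expect_equal(res3$n_splits_included, 1L)
    ## permutation invariance in the sample arguments
    expect_equal(asdsf(list(s_mix, s_ab, rep_sample(tr4_ab, 5)))$asdsf,
                 res3$asdsf)
    ## error distinct from asdsf == 0 when nothing passes the threshold
    s_weak <- mixed_sample(list(tr4_ab, tr4_star), c(1, 19))
    expect_error(asdsf(list(s_weak, rep_sample(tr4_star, 5)), minFreq = 0.10),
                 "no comparable splits")
})

test_that("unstable splits are flagged at SD > threshold, sorted", {
    expect_equal(nrow(flagUnstableSplits(list(rep_sample(tr4_ab, 4),
                                              rep_sample(tr4_ab, 4)))), 0L)
    fl <- flagUnstableSplits(list(rep_sample(tr4_ab, 10),
                                  rep_sample(tr4_ac, 10)))
    expect_equal(nrow(fl), 2L)
    expect_equal(fl$sd, rep(1 / sqrt(2), 2), tolerance = 1e-9)
    ## (0.55, 0.45): SD 0.0707 stays under the default threshold
    s1 <- mixed_sample(list(tr4_ab, tr4_star), c(11, 9))
    s2 <- mixed_sample(list(tr4_ab, tr4_star), c(9, 11))
    expect_equal(nrow(flagUnstableSplits(list(s1, s2))), 0L)
    expect_equal(nrow(flagUnstableSplits(list(s1, s2), sdThreshold = 0.05)), 1L)
})

test_that("restriction prunes trees, sums branch lengths, commutes with splits", {
    t5 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):2):1);")
    r <- restrictSample(treeSample(t5), c("A", "B", "C", "D"))
    pruned <- sampleTrees(r)[[1]]
    expect_identical(treeSplits(pruned), treeSplits(tr4_ab))
    ## branch lengths across the suppressed node sum (1 + 2 -> 3)
    d_len <- pruned$edge.length[pruned$edge[, 2] ==
                                which(pruned$tip.label == "D")]
    expect_equal(d_len, 3)
    ## identity restriction
    s <- rep_sample(t5, 3)
    expect_identical(restrictSample(s, taxa(s)), s)
    expect_error(restrictSample(s, c("A", "B", "C")), "4 taxa")

    ## splits(restrict(T, X)) == restriction of splits(T) to X minus trivial
    set.seed(5)
    for (i in 1:10) {
        tr <- ape::rtree(10)
        keep <- sort(sample(tr$tip.label, 6))
        direct <- treeSplits(ape::keep.tip(tr, keep))
        restr <- list()
        for (s0 in treeSplits(tr)) {
            s2 <- intersect(s0, keep)
            if (length(s2) < 2L || length(s2) > length(keep) - 2L) next
            if (sort(keep)[1L] %in% s2) s2 <- setdiff(keep, s2)
            restr[[paste(sort(s2), collapse = "|")]] <- sort(s2)
        }
        expect_setequal(vapply(direct, paste, "", collapse = "|"),
                        names(restr))
    }
})

test_that("majority consensus contains exactly the splits above threshold", {
    s <- rep_sample(tr4_ab, 8)
    cons <- majorityConsensus(s)
    expect_identical(treeSplits(cons), treeSplits(tr4_ab))
    expect_equal(unname(attr(cons, "support")), 1)

    cons6 <- majorityConsensus(mixed_sample(list(tr4_ab, tr4_ac), c(6, 4)))
    expect_identical(treeSplits(cons6), list(c("C", "D")))
    expect_equal(unname(attr(cons6, "support")), 0.6)

    ## strict rule: a 50/50 split is excluded -> star
    cons5 <- majorityConsensus(mixed_sample(list(tr4_ab, tr4_ac), c(5, 5)))
    expect_length(treeSplits(cons5), 0L)

    expect_error(majorityConsensus(s, threshold = 0.4), "0.5")
})

test_that("consensus supports equal split frequencies and match ape::consensus", {
    set.seed(31)
    for (i in 1:5) {
        tr <- ape::rtree(9)
        smp <- simTreeSample(tr, 30, nniMoves = 2, seed = 100 + i)
        cons <- majorityConsensus(smp)
        f <- splitFrequencies(splitFrequencyTable(smp))[, 1]
        sup <- attr(cons, "support")
        expect_true(all(sup > 0.5))
        expect_equal(unname(sup), unname(f[names(sup)]))
        ## independent oracle: same topology as ape majority-rule consensus
        ref <- ape::consensus(sampleTrees(smp), p = 0.5)
        expect_setequal(vapply(treeSplits(cons), paste, "", collapse = "|"),
                        vapply(treeSplits(ref), paste, "", collapse = "|"))
    }
})

test_that("resolution percent follows 100 k / (n - 3)", {
    expect_equal(resolutionPercent(ape::rtree(10)), 100)
    expect_equal(resolutionPercent(tr4_star), 0)
    ## 43 leaves, 38 splits -> 95.0 (collapse two non-root internal edges of
    ## an unrooted binary tree)
    set.seed(2)
    tr <- ape::unroot(ape::rtree(43))
    tr$edge.length <- rep(1, nrow(tr$edge))
    root <- length(tr$tip.label) + 1L
    internal <- which(tr$edge[, 2] > length(tr$tip.label) &
                      tr$edge[, 1] != root)
    tr$edge.length[internal[c(3, 17)]] <- 0
    partly <- ape::di2multi(tr)
    expect_length(treeSplits(partly), 38L)
    expect_equal(resolutionPercent(partly), 95.0)
})

test_that("subsampling follows the burn-in and even-spacing index rule", {
    ## trackable trees: tip 'A' pendant length encodes the tree's index
    mk <- function(i) {
        t <- tr4_ab
        t$edge.length <- rep(1, nrow(t$edge))
        t$edge.length[t$edge[, 2] == which(t$tip.label == "A")] <- i
        t
    }
    idx_of <- function(s) vapply(unclass(sampleTrees(s)), function(t)
        t$edge.length[t$edge[, 2] == which(t$tip.label == "A")], 0)

    s10 <- treeSample(lapply(1:10, mk))
    expect_equal(idx_of(subsampleTrees(s10, 0.25, 2)), c(3, 10))  # post 1 & 8
    expect_equal(idx_of(subsampleTrees(s10, 0, NULL)), 1:10)      # identity

    s40 <- treeSample(lapply(1:4000, mk))
    sub <- subsampleTrees(s40, 0.25, 1000)
    idx <- idx_of(sub)
    expect_length(idx, 1000L)
    expect_equal(idx[1], 1001)       # first post-burn-in tree
    expect_equal(idx[1000], 4000)    # last tree
    expect_true(all(diff(idx) >= 1))
    expect_error(subsampleTrees(s10, 0.25, 9), "exceeds")
})

test_that("patristic distances are path sums obeying the four-point condition", {
    expect_equal(patristicMatrix(ape::read.tree(text = "(A:1,B:2);"))$d["A", "B"], 3)
    pm <- patristicMatrix(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
    expect_equal(pm$d["A", "C"], 4)
    expect_equal(pm$d["A", "B"], 2)
    set.seed(13)
    for (i in 1:5) {
        tr <- ape::rtree(8)
        d <- patristicMatrix(tr)$d
        tips <- rownames(d)
        for (j in 1:10) {
            q <- sample(tips, 4)
            sums <- c(d[q[1], q[2]] + d[q[3], q[4]],
                      d[q[1], q[3]] + d[q[2], q[4]],
                      d[q[1], q[4]] + d[q[2], q[3]])
            expect_equal(sort(sums)[2], sort(sums)[3], tolerance = 1e-9)
        }
    }
    bad <- ape::read.tree(text = "(A:1,B:2);")
    bad$edge.length[2] <- NA
    expect_error(patristicMatrix(bad), "edge")
})
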