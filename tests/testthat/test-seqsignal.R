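test_that("site classification follows the stated definitions", {
    ## 4 taxa, columns AAAA / AAAC / AACC
    aln <- alignment(c(a = "AAA", b = "AAA", c = "AAC", d = "ACC"))
    sc <- classifySites(aln)
    expect_equal(sc$n_sites, 3L)
    expect_equal(sc$variable, 2L)
    expect_equal(sc$parsimony_informative, 1L)

    same <- alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
    expect_equal(classifySites(same)$variable, 0L)
    expect_equal(classifySites(same)$parsimony_informative, 0L)

    ## gaps/missing are not states: [A, A, -, ?] is constant
    gappy <- alignment(c(a = "A", b = "A", c = "-", d = "?"))
    expect_equal(classifySites(gappy)$constant, 1L)
    expect_equal(classifySites(gappy)$variable, 0L)

    expect_error(classifySites(aln, integer(0)), "empty partition")
    expect_error(classifySites(alignment(c(a = "ACGT"))), "2 taxa")
})

test_that("site classification is partition-additive", {
    set.seed(11)
    for (i in 1:20) {
        aln <- random_dna_alignment(5, 40)
        p1 <- 1:17; p2 <- 18:40
        s1 <- classifySites(aln, p1); s2 <- classifySites(aln, p2)
        su <- classifySites(aln)
        for (fld in c("n_sites", "constant", "variable",
                      "parsimony_informative", "unclassified"))
            expect_equal(s1[[fld]] + s2[[fld]], su[[fld]])
    }
})

test_that("base composition excludes gaps and ambiguities", {
    expect_equal(unname(baseComposition(alignment(c(a = "GGCC", b = "GGCC")))$gc),
                 c(1, 1))
    expect_equal(unname(baseComposition(alignment(c(a = "ACGT", b = "ACGT")))$gc[1]),
                 0.5)
    bc <- baseComposition(alignment(c(a = "AC-N", b = "ACGT")))
    expect_equal(unname(bc$counts["a", ]), c(1L, 1L, 0L, 0L))
    expect_equal(unname(bc$gc["a"]), 0.5)
    expect_warning(
        baseComposition(alignment(c(a = "----", b = "ACGT"))), "excluded")
})

test_that("stationarity chi-square matches the homogeneity formula", {
    same <- alignment(c(a = "AACCGGTT", b = "AACCGGTT"))
    st <- stationarityChi2(same)
    expect_equal(st$chi_square, 0)
    expect_equal(st$p_value, 1)
    expect_equal(st$df, 3L)  # (2-1) * (4-1)

    ## counts (10,10,10,10) vs (40,0,0,0): hand-computed homogeneity statistic
    a <- paste(rep(c("A", "C", "G", "T"), each = 10), collapse = "")
    b <- paste(rep("A", 40), collapse = "")
    aln <- alignment(c(x = a, y = b))
    obs <- rbind(c(10, 10, 10, 10), c(40, 0, 0, 0))
    E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    expect_equal(stationarityChi2(aln)$chi_square, sum((obs - E)^2 / E))

    ## invariant under taxon reordering; grows with compositional outliers
    expect_equal(stationarityChi2(alignment(c(y = b, x = a)))$chi_square,
                 stationarityChi2(aln)$chi_square)
    milder <- alignment(c(x = a,
        y = paste(rep(c("A", "C", "G", "T"), c(20, 8, 8, 4)), collapse = "")))
    expect_lt(stationarityChi2(milder)$chi_square,
              stationarityChi2(aln)$chi_square)
})

test_that("zero-count bases are dropped with df adjustment", {
    aln <- alignment(c(a = "AACC", b = "ACCC"))
    expect_warning(st <- stationarityChi2(aln), "dropped")
    expect_equal(st$df, 1L)  # 2 taxa x 2 observed bases
})

test_that("p-distances use pairwise deletion and record comparable sites", {
    expect_equal(pDistanceMatrix(alignment(c(a = "ACGT", b = "ACGT")))$d["a", "b"], 0)
    expect_equal(pDistanceMatrix(alignment(c(a = "ACGT", b = "TGCA")))$d["a", "b"], 1)
    pd <- pDistanceMatrix(alignment(c(a = "AC-T", b = "ACGT")))
    expect_equal(pd$d["a", "b"], 0)
    expect_equal(pd$comparable_sites["a", "b"], 3L)
    expect_warning(
        pd0 <- pDistanceMatrix(alignment(c(a = "A---", b = "-CGT"))),
        "zero comparable")
    expect_true(is.na(pd0$d["a", "b"]))
})

test_that("p-distances agree with the dist.dna oracle and are symmetric", {
    set.seed(21)
    for (i in 1:10) {
        aln <- random_dna_alignment(6, 60,
            alphabet = c("A", "C", "G", "T", "-"),
            prob = c(rep(0.23, 4), 0.08))
        d <- pDistanceMatrix(aln)$d
        expect_identical(d, t(d))
        expect_true(all(diag(d) == 0))
        expect_true(all(d >= 0 & d <= 1, na.rm = TRUE))
        bin <- ape::as.DNAbin(alignmentMatrix(aln))
        ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                       pairwise.deletion = TRUE))
        expect_equal(d[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
    }
})
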