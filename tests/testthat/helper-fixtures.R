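## Shared fixtures and independent brute-force oracles for the test suite.

tr4_ab <- ape::read.tree(text = "((A,B),(C,D));")
tr4_ac <- ape::read.tree(text = "((A,C),(B,D));")
tr4_star <- ape::read.tree(text = "(A,B,C,D);")

rep_sample <- function(tree, n) treeSample(rep(c(tree), n))

mixed_sample <- function(trees, counts) {
    treeSample(do.call(c, mapply(function(t, k) rep(c(t), k), trees, counts,
                                 SIMPLIFY = FALSE)))
}

random_dna_alignment <- function(n_taxa, n_cols,
                                 alphabet = c("A", "C", "G", "T", "-", "?", "N"),
                                 prob = c(rep(0.2, 4), 0.1, 0.05, 0.05)) {
    m <- matrix(sample(alphabet, n_taxa * n_cols, replace = TRUE, prob = prob),
                n_taxa, n_cols,
                dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
    alignment(m)
}

## Definitional site-classification oracle: per column, direct enumeration of
## unambiguous base counts.
oracle_classify <- function(m) {
    bases <- c("A", "C", "G", "T")
    n_var <- 0L; n_pars <- 0L; n_unclass <- 0L
    for (j in seq_len(ncol(m))) {
        counts <- sapply(bases, function(b) sum(m[, j] == b))
        counts <- counts[counts > 0]
        if (length(counts) == 0L) n_unclass <- n_unclass + 1L
        if (length(counts) >= 2L) n_var <- n_var + 1L
        if (sum(counts >= 2L) >= 2L) n_pars <- n_pars + 1L
    }
    list(n_sites = ncol(m), constant = ncol(m) - n_var - n_unclass,
         variable = n_var, parsimony_informative = n_pars,
         unclassified = n_unclass)
}

## Exhaustive rogue oracle over all dropsets of size <= max_size, with the
## same tie-breaking (gain desc, size asc, lexicographic label tuple asc).
oracle_best_dropset <- function(sample, max_size = 2, threshold = 0.5) {
    tx <- taxa(sample)
    cands <- as.list(tx)
    if (max_size >= 2) {
        cands <- c(cands, combn(tx, 2, simplify = FALSE))
    }
    cands <- Filter(function(ds) length(tx) - length(ds) >= 4, cands)
    gains <- vapply(cands, function(ds) supportGain(sample, ds, threshold), 0)
    key <- vapply(cands, function(ds) paste(sort(ds), collapse = ","), "")
    ord <- order(-gains, lengths(cands), key)
    list(dropset = sort(cands[[ord[1L]]]), gain = gains[ord[1L]])
}

## A sample over a fixed backbone where rogue R attaches once to each edge:
## dropping R restores every backbone split to frequency 1.
rogue_carousel_sample <- function() {
    backbone <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
    trees <- lapply(seq_len(nrow(backbone$edge)), function(j) {
        tip <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                              tip.label = "R", edge.length = 1,
                              Nnode = 1L), class = "phylo")
        ape::bind.tree(backbone, tip, where = backbone$edge[j, 2L],
                       position = backbone$edge.length[j] / 2)
    })
    treeSample(trees)
}
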