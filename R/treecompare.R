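## Split-based statistics over tree samples: bipartition extraction, split
## frequencies, ASDSF, majority-rule consensus, resolution, restriction,
## burn-in/subsampling and patristic distances.  All split computations treat
## trees as unrooted; rooted input is unrooted first.
##
## A bipartition is stored canonically as the side NOT containing the
## lexicographically smallest taxon of the current taxon set, as a sorted
## label vector; the paste()d key is used for counting.

.SPLIT_SEP <- "\x01"

.split_key <- function(side) paste(side, collapse = .SPLIT_SEP)

.key_to_side <- function(key) strsplit(key, .SPLIT_SEP, fixed = TRUE)[[1L]]

## Canonicalize a side (label vector) against a taxon set: returns the sorted
## side not containing the smallest taxon, or NULL if trivial.
.canonical_side <- function(side, taxa) {
    k <- length(side)
    if (k < 2L || k > length(taxa) - 2L) return(NULL)
    small <- taxa[1L]  # taxa assumed sorted
    if (small %in% side) side <- setdiff(taxa, side)
    sort(side)
}

## Non-trivial bipartitions of one tree, as canonical sides.
.tree_sides <- function(phy) {
    if (anyDuplicated(phy$tip.label))
        stop("duplicate leaf labels: ",
             phy$tip.label[duplicated(phy$tip.label)][1L])
    n <- length(phy$tip.label)
    if (n < 4L) return(list())
    phy <- ape::unroot(phy)
    phy <- stats::reorder(phy, "postorder")
    E <- phy$edge
    below <- vector("list", n + phy$Nnode)
    below[seq_len(n)] <- as.list(seq_len(n))
    for (k in seq_len(nrow(E))) {
        p <- E[k, 1L]; ch <- E[k, 2L]
        below[[p]] <- c(below[[p]], below[[ch]])
    }
    taxa <- sort(phy$tip.label)
    sides <- list()
    for (k in seq_len(nrow(E))) {
        ch <- E[k, 2L]
        if (ch <= n) next  # pendant edge -> trivial split
        s <- .canonical_side(phy$tip.label[below[[ch]]], taxa)
        if (!is.null(s)) sides[[length(sides) + 1L]] <- s
    }
    unique(sides)
}

#' Non-trivial bipartitions of a tree
#'
#' Returns the bipartitions induced by the internal edges of the unrooted
#' topology, canonicalized as the side not containing the lexicographically
#' smallest taxon.  A binary unrooted tree on `n` leaves yields exactly
#' `n - 3` splits; a star tree yields none.
#'
#' @param tree A `phylo` object.
#' @return List of character vectors (sorted label sets).
#' @examples
#' treeSplits(ape::read.tree(text = "((A,B),(C,D));"))
#' @export
treeSplits <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    .tree_sides(tree)
}

.as_sample_list <- function(samples) {
    if (is(samples, "TreeSample")) samples <- list(samples)
    stopifnot(is.list(samples), length(samples) >= 1L)
    lapply(samples, function(s) stopifnot(is(s, "TreeSample")))
    if (is.null(names(samples)) || any(!nzchar(names(samples))))
        names(samples) <- paste0("sample", seq_along(samples))
    samples
}

## Per-tree canonical split keys for a whole sample.
.sample_split_keys <- function(sample) {
    lapply(unclass(sample@trees),
           function(t) vapply(.tree_sides(t), .split_key, ""))
}

#' Split-frequency table over one or more tree samples
#'
#' The frequency of a split in a sample is the fraction of that sample's
#' trees containing it; a split absent from a sample has frequency 0 there.
#' The across-sample standard deviation (see [asdsf()],
#' [flagUnstableSplits()]) uses the sample (n-1) denominator, the convention
#' behind MrBayes-style ASDSF values.
#'
#' @param samples A [TreeSample-class] or (named) list of them, all over the
#'   same taxon set.
#' @return A [SplitFrequencyTable-class].
#' @export
splitFrequencyTable <- function(samples) {
    samples <- .as_sample_list(samples)
    taxa <- sort(samples[[1L]]@taxa)
    for (s in samples[-1L]) {
        if (!identical(sort(s@taxa), taxa))
            stop("samples are over different taxon sets; restrict them to ",
                 "the shared taxa first (restrictSample)")
    }
    per_sample <- lapply(samples, function(s) {
        keys <- .sample_split_keys(s)
        tab <- table(unlist(keys))
        as.numeric(tab) / length(keys) -> f
        stats::setNames(f, names(tab))
    })
    all_keys <- sort(unique(unlist(lapply(per_sample, names))))
    f <- vapply(per_sample, function(v) {
        out <- stats::setNames(numeric(length(all_keys)), all_keys)
        out[names(v)] <- v
        out
    }, numeric(length(all_keys)))
    if (length(all_keys) == 0L)
        f <- matrix(numeric(0), 0L, length(samples))
    if (is.null(dim(f))) f <- matrix(f, nrow = length(all_keys))
    colnames(f) <- names(samples)
    new("SplitFrequencyTable", taxa = taxa, freq = f,
        splits = lapply(all_keys, .key_to_side))
}

#' Average standard deviation of split frequencies (ASDSF)
#'
#' The mean, over all splits whose frequency reaches `minFreq` in at least
#' one sample, of the across-sample standard deviation (n-1 denominator) of
#' that split's frequencies.  Used as a topological distance between tree
#' samples; identical samples give 0, and for two samples the value is
#' bounded by `sqrt(2)/2`.
#'
#' @param samples Two or more [TreeSample-class] objects (list), or a
#'   precomputed [SplitFrequencyTable-class] with >= 2 sample columns.
#' @param minFreq Inclusion threshold in `[0, 1)` (default 0.10, the MrBayes
#'   `minpartfreq` convention).
#' @return List with `asdsf`, `n_splits_included`, `min_freq`, and
#'   `n_shared_taxa`.
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D));")
#' t2 <- ape::read.tree(text = "((A,C),(B,D));")
#' s1 <- treeSample(rep(c(t1), 10))
#' s2 <- treeSample(rep(c(t2), 10))
#' asdsf(list(s1, s2))$asdsf  # sqrt(1/2) over the two discordant splits
#' @export
asdsf <- function(samples, minFreq = 0.10) {
    stopifnot(minFreq >= 0, minFreq < 1)
    sft <- if (is(samples, "SplitFrequencyTable")) samples
           else splitFrequencyTable(samples)
    if (ncol(sft@freq) < 2L) stop("need at least two samples")
    keep <- apply(sft@freq, 1L, max) >= minFreq
    if (!any(keep)) stop("no comparable splits at minFreq = ", minFreq)
    sds <- apply(sft@freq[keep, , drop = FALSE], 1L, stats::sd)
    list(asdsf = mean(sds), n_splits_included = sum(keep),
         min_freq = minFreq, n_shared_taxa = length(sft@taxa))
}

#' Flag splits with unstable frequencies between samples
#'
#' Returns exactly the splits whose across-sample standard deviation of
#' frequencies exceeds `sdThreshold`, in descending SD order, mirroring the
#' practice of scanning MCMC runs for bipartitions with SD > 0.1 whose
#' support may not have been estimated accurately.
#'
#' @inheritParams asdsf
#' @param sdThreshold Flagging threshold (default 0.1).
#' @return data.frame with `split` (labels joined by `|`), `sd`, and one
#'   frequency column per sample.
#' @export
flagUnstableSplits <- function(samples, sdThreshold = 0.1) {
    sft <- if (is(samples, "SplitFrequencyTable")) samples
           else splitFrequencyTable(samples)
    if (ncol(sft@freq) < 2L) stop("need at least two samples")
    f <- splitFrequencies(sft)
    sds <- apply(f, 1L, stats::sd)
    keep <- which(sds > sdThreshold)
    keep <- keep[order(sds[keep], decreasing = TRUE)]
    out <- data.frame(split = rownames(f)[keep], sd = sds[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
    cbind(out, as.data.frame(f[keep, , drop = FALSE], row.names = NULL))
}

#' Restrict a tree sample to a taxon subset
#'
#' Prunes every tree to `taxa`, suppressing degree-2 nodes and summing the
#' incident branch lengths, so that the split set of each pruned tree equals
#' the restriction of the original split set (minus trivialized splits).
#'
#' @param sample A [TreeSample-class].
#' @param taxa Character vector, subset of the sample's taxa, length >= 4.
#' @return A [TreeSample-class] over `taxa`.
#' @export
restrictSample <- function(sample, taxa) {
    stopifnot(is(sample, "TreeSample"))
    if (!all(taxa %in% sample@taxa))
        stop("taxa not in sample: ",
             paste(setdiff(taxa, sample@taxa), collapse = ", "))
    if (length(taxa) < 4L) stop("restriction needs at least 4 taxa")
    if (setequal(taxa, sample@taxa)) return(sample)
    pruned <- lapply(unclass(sample@trees), ape::keep.tip, tip = taxa)
    treeSample(pruned, origin = sample@origin)
}

#' Majority-rule consensus tree with support values
#'
#' Contains exactly the splits whose frequency is strictly greater than
#' `threshold` (default 0.5; thresholds >= 0.5 guarantee pairwise
#' compatibility, so a split at exactly 0.5 in a two-tree sample is
#' excluded).  Each internal edge is annotated with its split frequency as a
#' node label.
#'
#' @param sample A [TreeSample-class] over a common taxon set.
#' @param threshold Consensus threshold in `[0.5, 1)`.
#' @return A `phylo` tree with `$node.label` support values (empty string at
#'   the root) and attributes `threshold` and `support` (named frequency
#'   vector keyed by split).
#' @export
majorityConsensus <- function(sample, threshold = 0.5) {
    stopifnot(is(sample, "TreeSample"))
    if (threshold < 0.5)
        stop("threshold < 0.5 does not guarantee compatible splits")
    if (threshold >= 1) stop("threshold must be < 1")
    sft <- splitFrequencyTable(list(sample))
    freqs <- as.numeric(sft@freq[, 1L])
    keep <- which(freqs > threshold)
    clades <- sft@splits[keep]   # canonical sides exclude the smallest taxon
    supports <- freqs[keep]
    taxa <- sft@taxa
    tree <- .tree_from_clades(taxa, clades, supports)
    attr(tree, "threshold") <- threshold
    attr(tree, "support") <- stats::setNames(
        supports, vapply(clades, paste, "", collapse = "|"))
    tree
}

## Build a phylo from a laminar family of clades (none containing the
## reference taxon taxa[1]), each with a support value.
.tree_from_clades <- function(taxa, clades, supports) {
    fmt <- function(x) format(x, digits = 10, trim = TRUE, scientific = FALSE)
    build <- function(members, inside) {
        ## inside: indices of clades strictly contained in members, not yet
        ## emitted.  Pick the maximal ones, recurse.
        used <- rep(FALSE, length(inside))
        parts <- character(0)
        sizes <- lengths(clades[inside])
        for (i in order(sizes, decreasing = TRUE)) {
            if (used[i]) next
            ci <- inside[i]
            within <- inside[vapply(inside, function(cj)
                cj != ci && all(clades[[cj]] %in% clades[[ci]]), TRUE) &
                !used]
            used[match(within, inside)] <- TRUE
            used[i] <- TRUE
            parts <- c(parts,
                       paste0(build(clades[[ci]], within),
                              fmt(supports[ci])))
        }
        singles <- setdiff(members, unlist(clades[inside]))
        parts <- c(parts, sort(singles))
        paste0("(", paste(parts, collapse = ","), ")")
    }
    top <- seq_along(clades)
    nwk <- paste0(build(taxa, top), ";")
    ape::read.tree(text = nwk)
}

#' Resolution of a consensus tree
#'
#' The percentage of the `n - 3` possible internal edges of an unrooted
#' binary tree on `n` leaves that are present: `100 * k / (n - 3)` where `k`
#' is the number of non-trivial splits.
#'
#' @param tree A `phylo` tree (e.g. from [majorityConsensus()]).
#' @return Numeric percentage in `[0, 100]`.
#' @export
resolutionPercent <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    n <- length(tree$tip.label)
    if (n < 4L) stop("resolution needs >= 4 leaves")
    100 * length(.tree_sides(tree)) / (n - 3L)
}

#' Burn-in removal and evenly spaced subsampling
#'
#' Discards the first `floor(burninFraction * N)` trees, then takes `nOut`
#' evenly spaced trees from the remainder; for `nOut >= 2` the first and last
#' post-burn-in trees are always included, and fractional spacing ties
#' resolve toward earlier indices.
#'
#' @param sample A [TreeSample-class].
#' @param burninFraction Fraction in `[0, 1)` discarded from the front.
#' @param nOut Number of trees to keep (defaults to all post-burn-in trees).
#' @return A [TreeSample-class].
#' @export
subsampleTrees <- function(sample, burninFraction = 0.25, nOut = NULL) {
    stopifnot(is(sample, "TreeSample"),
              burninFraction >= 0, burninFraction < 1)
    N <- length(sample@trees)
    drop <- floor(burninFraction * N)
    M <- N - drop
    if (is.null(nOut)) nOut <- M
    if (nOut > M) stop("nOut = ", nOut, " exceeds the ", M,
                       " post-burn-in trees")
    if (nOut < 1L) stop("nOut must be >= 1")
    ## ceiling(x - 0.5) rounds halves down (ties toward earlier indices); the
    ## epsilon guards against upward floating noise at exact halves.
    idx <- if (nOut == 1L) 1L
           else as.integer(ceiling(seq(1, M, length.out = nOut) - 0.5 - 1e-9))
    idx[1L] <- 1L; idx[nOut] <- M
    treeSample(unclass(sample@trees)[drop + idx], origin = sample@origin)
}

#' Patristic distance matrix of a tree
#'
#' Distance between two leaves is the sum of branch lengths on the unique
#' path connecting them.
#'
#' @param tree A `phylo` with branch lengths on every edge.
#' @return List with `d` (symmetric matrix, taxa in sorted order) and
#'   `kind = "patristic"`.
#' @export
patristicMatrix <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    if (is.null(tree$edge.length))
        stop("tree has no branch lengths")
    bad <- which(is.na(tree$edge.length))
    if (length(bad))
        stop("missing branch length on edge ", bad[1L], " (",
             tree$edge[bad[1L], 1L], " -> ", tree$edge[bad[1L], 2L], ")")
    d <- stats::cophenetic(tree)
    ord <- sort(rownames(d))
    list(d = d[ord, ord], kind = "patristic")
}
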