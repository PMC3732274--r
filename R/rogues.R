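## Rogue-taxon detection by dropset optimization: find taxa (or small sets)
## whose removal maximally increases the summed support of the majority-rule
## consensus of a tree sample.
##
## Support computations work on precomputed per-tree split sets: restricting
## a sample to a taxon subset restricts each tree's splits directly (removing
## the dropped taxa from each side, re-canonicalizing, de-duplicating within
## each tree), which is equivalent to pruning the trees and recomputing.

## sides_per_tree: list (one element per tree) of lists of canonical sides.
.sides_per_tree <- function(sample) {
    lapply(unclass(sample@trees), .tree_sides)
}

## Frequencies of restricted splits given per-tree split sides.
.restricted_freqs <- function(sides_per_tree, taxa_kept) {
    taxa_kept <- sort(taxa_kept)
    keys <- lapply(sides_per_tree, function(sides) {
        ks <- character(0)
        for (s in sides) {
            s2 <- s[s %in% taxa_kept]
            s2 <- .canonical_side(s2, taxa_kept)
            if (!is.null(s2)) ks <- c(ks, .split_key(s2))
        }
        unique(ks)
    })
    tab <- table(unlist(keys))
    stats::setNames(as.numeric(tab) / length(keys), names(tab))
}

.support_sum <- function(freqs, threshold) sum(freqs[freqs > threshold])

.resolution_from_freqs <- function(freqs, n_taxa, threshold) {
    100 * sum(freqs > threshold) / (n_taxa - 3L)
}

#' Raw support improvement of a dropset
#'
#' The sum of split supports (frequencies in `[0, 1]`) in the majority-rule
#' consensus of the sample restricted to the remaining taxa, minus the same
#' sum for the full sample.  The empty dropset gives exactly 0.
#'
#' @param sample A [TreeSample-class] over a common taxon set.
#' @param dropset Character vector of taxa to remove (may be empty).
#' @param threshold Majority-rule threshold (default 0.5).
#' @return Numeric raw improvement, in support units.
#' @export
supportGain <- function(sample, dropset, threshold = 0.5) {
    stopifnot(is(sample, "TreeSample"))
    dropset <- as.character(dropset)
    if (!all(dropset %in% sample@taxa))
        stop("dropset taxa not in sample: ",
             paste(setdiff(dropset, sample@taxa), collapse = ", "))
    kept <- setdiff(sample@taxa, dropset)
    if (length(kept) < 4L) stop("dropset leaves fewer than 4 taxa")
    spt <- .sides_per_tree(sample)
    full <- .support_sum(.restricted_freqs(spt, sample@taxa), threshold)
    restr <- .support_sum(.restricted_freqs(spt, kept), threshold)
    restr - full
}

## Deterministic candidate ordering: larger gain first, then smaller dropset,
## then lexicographically smallest taxon tuple.
.better_candidate <- function(gain_a, set_a, gain_b, set_b) {
    if (is.null(set_b)) return(TRUE)
    if (gain_a != gain_b) return(gain_a > gain_b)
    if (length(set_a) != length(set_b))
        return(length(set_a) < length(set_b))
    paste(sort(set_a), collapse = ",") < paste(sort(set_b), collapse = ",")
}

#' Greedy rogue-taxon dropset search
#'
#' Repeatedly finds the dropset (up to `maxDropsetSize` taxa) whose removal
#' most increases the summed majority-rule consensus support, accepts it if
#' the raw improvement reaches `minRawImprovement`, removes those taxa, and
#' iterates until no candidate passes.  Singleton dropsets are scored
#' exhaustively; larger sets are grown by best-first extension of the top
#' `beamWidth` candidates of the previous size.  Ties resolve toward smaller
#' dropsets, then lexicographically smaller taxon tuples, making the report
#' deterministic.
#'
#' @param sample A [TreeSample-class] over >= 5 taxa.
#' @param maxDropsetSize Maximum taxa per dropset (1..10).
#' @param threshold Majority-rule threshold (default 0.5).
#' @param minRawImprovement Acceptance cutoff on the raw improvement, in
#'   support units (default 0.5).
#' @param beamWidth Beam width for multi-taxon extension (default 5).
#' @return A [RogueReport-class]; empty when nothing passes the cutoff.
#' @seealso [supportGain()], [rogueTable()]
#' @export
findRogues <- function(sample, maxDropsetSize = 1, threshold = 0.5,
                       minRawImprovement = 0.5, beamWidth = 5) {
    stopifnot(is(sample, "TreeSample"))
    stopifnot(maxDropsetSize >= 1, maxDropsetSize <= 10)
    if (length(sample@taxa) < 5L) stop("need at least 5 taxa")
    spt <- .sides_per_tree(sample)
    current <- sort(sample@taxa)

    dropsets <- list(); raw <- numeric(0); rel <- numeric(0)
    res_before <- numeric(0); res_after <- numeric(0)

    repeat {
        base_freqs <- .restricted_freqs(spt, current)
        base_support <- .support_sum(base_freqs, threshold)
        score <- function(ds) {
            kept <- setdiff(current, ds)
            if (length(kept) < 4L) return(-Inf)
            .support_sum(.restricted_freqs(spt, kept), threshold) -
                base_support
        }
        ## exhaustive singletons
        cand_sets <- as.list(current)
        cand_gain <- vapply(cand_sets, score, 0)
        best_set <- NULL; best_gain <- -Inf
        for (i in seq_along(cand_sets)) {
            if (.better_candidate(cand_gain[i], cand_sets[[i]],
                                  best_gain, best_set)) {
                best_gain <- cand_gain[i]; best_set <- cand_sets[[i]]
            }
        }
        ## beam extension to larger dropsets
        beam_idx <- order(cand_gain, decreasing = TRUE)
        beam <- cand_sets[utils::head(beam_idx, beamWidth)]
        size <- 1L
        while (size < maxDropsetSize && length(beam)) {
            ext_sets <- list(); ext_gain <- numeric(0)
            for (b in beam) {
                for (t in setdiff(current, b)) {
                    ds <- sort(c(b, t))
                    key <- paste(ds, collapse = ",")
                    if (key %in% names(ext_gain)) next
                    g <- score(ds)
                    ext_sets[[key]] <- ds
                    ext_gain[key] <- g
                }
            }
            if (!length(ext_sets)) break
            for (key in names(ext_sets)) {
                if (.better_candidate(ext_gain[[key]], ext_sets[[key]],
                                      best_gain, best_set)) {
                    best_gain <- ext_gain[[key]]; best_set <- ext_sets[[key]]
                }
            }
            keep <- utils::head(order(ext_gain, decreasing = TRUE), beamWidth)
            beam <- unname(ext_sets[keep])
            size <- size + 1L
        }
        if (is.null(best_set) || best_gain < minRawImprovement) break
        kept <- setdiff(current, best_set)
        after_freqs <- .restricted_freqs(spt, kept)
        dropsets[[length(dropsets) + 1L]] <- best_set
        raw <- c(raw, best_gain)
        rel <- c(rel, if (base_support > 0) best_gain / base_support else NA_real_)
        res_before <- c(res_before,
            .resolution_from_freqs(base_freqs, length(current), threshold))
        res_after <- c(res_after,
            .resolution_from_freqs(after_freqs, length(kept), threshold))
        current <- kept
        if (length(current) < 5L) break
    }
    ord <- order(raw, decreasing = TRUE)
    new("RogueReport",
        dropsets = dropsets[ord], rawImprovement = raw[ord],
        relativeImprovement = rel[ord],
        resolutionBefore = res_before[ord], resolutionAfter = res_after[ord],
        settings = list(maxDropsetSize = maxDropsetSize,
                        threshold = threshold,
                        minRawImprovement = minRawImprovement,
                        beamWidth = beamWidth,
                        acceptanceOrder = dropsets))
}
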