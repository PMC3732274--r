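## Alignment-level data-property statistics.  Everywhere in this file the only
## character states are A, C, G, T: gaps ('-'), missing ('?') and IUPAC
## ambiguity codes are non-states (the PAUP*/MEGA default policy).

.resolve_partition <- function(aln, partition) {
    nc <- ncol(aln@seqs)
    if (is.null(partition)) return(seq_len(nc))
    if (is.character(partition) && length(partition) == 1L) {
        if (!partition %in% names(aln@partitions))
            stop("unknown partition '", partition, "'")
        partition <- aln@partitions[[partition]]
    }
    partition <- as.integer(partition)
    if (!length(partition)) stop("empty partition")
    if (any(partition < 1L | partition > nc))
        stop("partition indices outside [1, ", nc, "]")
    partition
}

#' Classify alignment sites
#'
#' Counts constant, variable and parsimony-informative columns.  A column is
#' variable iff at least two distinct unambiguous bases occur in it, and
#' parsimony-informative iff at least two bases each occur in at least two
#' taxa.  Columns with fewer than one unambiguous base (e.g. all-gap) are
#' counted in `n_sites` but are neither constant nor variable.
#'
#' @param aln An [Alignment-class].
#' @param partition Optional column index vector or partition name.
#' @return List with `n_sites`, `constant`, `variable`,
#'   `parsimony_informative`, and `unclassified` (columns with no unambiguous
#'   base).
#' @examples
#' aln <- alignment(c(a = "AAA", b = "AAA", c = "ACC", d = "ACC"))
#' classifySites(aln)
#' @export
classifySites <- function(aln, partition = NULL) {
    stopifnot(is(aln, "Alignment"))
    if (nrow(aln@seqs) < 2L) stop("need at least 2 taxa")
    idx <- .resolve_partition(aln, partition)
    m <- aln@seqs[, idx, drop = FALSE]
    n_var <- 0L; n_pars <- 0L; n_unclass <- 0L
    for (j in seq_len(ncol(m))) {
        tab <- table(m[, j][m[, j] %in% .DNA_BASES])
        if (!length(tab)) { n_unclass <- n_unclass + 1L; next }
        if (length(tab) >= 2L) n_var <- n_var + 1L
        if (sum(tab >= 2L) >= 2L) n_pars <- n_pars + 1L
    }
    list(n_sites = length(idx),
         constant = length(idx) - n_var - n_unclass,
         variable = n_var,
         parsimony_informative = n_pars,
         unclassified = n_unclass)
}

#' Per-taxon base composition and GC content
#'
#' @inheritParams classifySites
#' @return List with `counts` (taxon x A/C/G/T integer matrix), `gc`
#'   (per-taxon GC fraction; `NA` for taxa with no unambiguous cell, which are
#'   flagged with a warning and excluded from the pooled value), and
#'   `gc_pooled`.
#' @export
baseComposition <- function(aln, partition = NULL) {
    stopifnot(is(aln, "Alignment"))
    idx <- .resolve_partition(aln, partition)
    m <- aln@seqs[, idx, drop = FALSE]
    counts <- t(apply(m, 1L, function(s)
        vapply(.DNA_BASES, function(b) sum(s == b), 0L)))
    colnames(counts) <- .DNA_BASES
    tot <- rowSums(counts)
    gc <- ifelse(tot > 0, (counts[, "C"] + counts[, "G"]) / tot, NA_real_)
    if (any(tot == 0))
        warning("taxa with no unambiguous cells excluded from pooled GC: ",
                paste(rownames(m)[tot == 0], collapse = ", "))
    pooled <- colSums(counts)
    list(counts = counts, gc = gc,
         gc_pooled = (pooled[["C"]] + pooled[["G"]]) / sum(pooled))
}

#' Chi-square test of base-compositional stationarity
#'
#' Homogeneity chi-square on the taxon-by-base count table: expected counts
#' are the pooled base frequencies scaled to each taxon's total, the statistic
#' is the usual sum of `(O-E)^2/E` (no continuity correction), and the
#' p-value is the upper tail of the chi-square distribution with
#' `(taxa - 1) * (bases - 1)` degrees of freedom.  Bases with zero pooled
#' count are dropped (with a warning) and the degrees of freedom adjusted;
#' taxa with no unambiguous cells are excluded likewise.
#'
#' @inheritParams classifySites
#' @return List with `chi_square`, `df`, `p_value`, and the count `table`
#'   used.
#' @export
stationarityChi2 <- function(aln, partition = NULL) {
    stopifnot(is(aln, "Alignment"))
    counts <- baseComposition(aln, partition)$counts
    keep_taxa <- rowSums(counts) > 0
    if (sum(keep_taxa) < 2L)
        stop("need at least 2 taxa with unambiguous bases")
    counts <- counts[keep_taxa, , drop = FALSE]
    keep_base <- colSums(counts) > 0
    if (!all(keep_base)) {
        warning("base(s) with zero pooled count dropped: ",
                paste(colnames(counts)[!keep_base], collapse = ", "))
        counts <- counts[, keep_base, drop = FALSE]
    }
    rt <- rowSums(counts); ct <- colSums(counts); N <- sum(counts)
    E <- outer(rt, ct) / N
    chi2 <- sum((counts - E)^2 / E)
    df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
    list(chi_square = chi2, df = df,
         p_value = pchisq(chi2, df, lower.tail = FALSE),
         table = counts)
}

#' Uncorrected pairwise p-distances
#'
#' Pairwise-deletion p-distance: for each taxon pair, the fraction of
#' mismatching sites among the sites where both taxa carry an unambiguous
#' base.  Pairs with no comparable site get `NA` with a warning.
#'
#' @inheritParams classifySites
#' @return List with `d` (symmetric distance matrix, zero diagonal, values in
#'   `[0,1]`), `comparable_sites` (integer matrix of per-pair site counts),
#'   and `kind = "p_distance"`.
#' @export
pDistanceMatrix <- function(aln, partition = NULL) {
    stopifnot(is(aln, "Alignment"))
    if (nrow(aln@seqs) < 2L) stop("need at least 2 taxa")
    idx <- .resolve_partition(aln, partition)
    m <- aln@seqs[, idx, drop = FALSE]
    code <- match(m, .DNA_BASES, nomatch = 0L)
    dim(code) <- dim(m)
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    comp <- matrix(0L, n, n, dimnames = dimnames(d))
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            ok <- code[i, ] > 0L & code[j, ] > 0L
            nc <- sum(ok)
            comp[i, j] <- comp[j, i] <- nc
            if (nc == 0L) {
                d[i, j] <- d[j, i] <- NA_real_
            } else {
                d[i, j] <- d[j, i] <- sum(code[i, ok] != code[j, ok]) / nc
            }
        }
    }
    if (anyNA(d))
        warning("pair(s) with zero comparable sites reported as NA")
    list(d = d, comparable_sites = comp, kind = "p_distance")
}
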