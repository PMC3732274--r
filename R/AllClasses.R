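#' @import methods
#' @importFrom stats median pchisq qgamma rexp runif sd setNames
#' @importFrom utils head tail
NULL

## Nucleotide state vocabulary shared across the package.  The four bases are
## the only characters ever treated as states; IUPAC ambiguity codes, '-' and
## '?' are retained on input but are non-states in every statistic.
.DNA_BASES <- c("A", "C", "G", "T")
.DNA_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.DNA_GAPS  <- c("-", "?")
.DNA_ALPHABET <- c(.DNA_BASES, .DNA_AMBIG, .DNA_GAPS)

.GROUP_VOCAB <- c("ingroup", "outgroup")

#' Multiple sequence alignment container
#'
#' A nucleotide multiple sequence alignment stored as a taxon-by-column
#' character matrix over the alphabet `A C G T`, the IUPAC ambiguity codes,
#' `-` (gap) and `?` (missing).  `U` is normalised to `T` and lower case to
#' upper case on construction.  An optional set of named partitions maps
#' partition names to 1-based column index vectors (genes, codon positions).
#'
#' @slot seqs Character matrix, rows named by taxon, one column per site.
#' @slot partitions Named list of integer vectors of column indices.
#' @seealso [alignment()], [readAlignment()], [classifySites()]
#' @export
setClass("Alignment",
    representation(seqs = "matrix", partitions = "list"))

setValidity("Alignment", function(object) {
    s <- object@seqs
    if (!is.character(s)) return("seqs must be a character matrix")
    tx <- rownames(s)
    if (is.null(tx) || any(!nzchar(tx))) return("taxon labels must be non-empty")
    if (anyDuplicated(tx)) {
        return(paste0("duplicate taxon label: ", tx[duplicated(tx)][1L]))
    }
    bad <- setdiff(unique(as.vector(s)), .DNA_ALPHABET)
    if (length(bad)) {
        return(paste0("unknown symbol(s) in alignment: ",
                      paste(bad, collapse = " ")))
    }
    p <- object@partitions
    if (length(p)) {
        if (is.null(names(p)) || any(!nzchar(names(p))))
            return("partitions must be named")
        for (nm in names(p)) {
            idx <- p[[nm]]
            if (any(idx < 1L | idx > ncol(s)))
                return(paste0("partition '", nm, "' outside [1, ", ncol(s), "]"))
            if (anyDuplicated(idx))
                return(paste0("partition '", nm, "' has duplicate columns"))
        }
    }
    TRUE
})

#' Ordered collection of trees over one taxon set
#'
#' Wraps an [ape::multiPhylo] list of trees that (unless constructed with
#' `allowHeterogeneous = TRUE`) all share the same leaf-label set.  Tree order
#' is meaningful: burn-in removal and evenly spaced subsampling act on it.
#'
#' @slot trees A `multiPhylo` object.
#' @slot taxa Character vector: union of leaf labels, sorted.
#' @slot origin Free-text provenance string.
#' @seealso [treeSample()], [readTreeSample()], [asdsf()]
#' @export
setClass("TreeSample",
    representation(trees = "ANY", taxa = "character", origin = "character"))

setValidity("TreeSample", function(object) {
    trs <- object@trees
    if (!inherits(trs, "multiPhylo")) return("trees must be a multiPhylo")
    if (length(trs) < 1L) return("a TreeSample needs at least one tree")
    labs <- unique(sort(unlist(lapply(trs, function(t) t$tip.label))))
    if (!identical(labs, sort(object@taxa)))
        return("taxa slot must equal the union of leaf labels")
    for (t in trs) if (anyDuplicated(t$tip.label))
        return("duplicate leaf labels within a tree")
    TRUE
})

#' Taxon-by-gene presence matrix
#'
#' Boolean presence/absence of each gene for each taxon, with per-taxon group
#' tags (`ingroup`/`outgroup`) and optional family and superfamily tags used
#' by the census operations.
#'
#' @slot present Logical matrix, rows = taxa, columns = genes.
#' @slot taxa A data.frame with columns `taxon`, `group`, and optionally
#'   `family`, `superfamily`.
#' @seealso [readPresenceMatrix()], [coverageStats()], [taxonCensus()]
#' @export
setClass("PresenceMatrix",
    representation(present = "matrix", taxa = "data.frame"))

setValidity("PresenceMatrix", function(object) {
    m <- object@present
    if (!is.logical(m)) return("present must be a logical matrix")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("present needs taxon rownames and gene colnames")
    if (nrow(object@taxa) != nrow(m))
        return("taxa table and presence matrix disagree on taxon count")
    if (!all(c("taxon", "group") %in% colnames(object@taxa)))
        return("taxa table needs 'taxon' and 'group' columns")
    if (!identical(object@taxa$taxon, rownames(m)))
        return("taxa table order must match presence matrix rows")
    if (!all(object@taxa$group %in% .GROUP_VOCAB))
        return(paste0("group tags must be one of: ",
                      paste(.GROUP_VOCAB, collapse = ", ")))
    TRUE
})

#' Per-sample bipartition frequencies
#'
#' For one or more tree samples over a common taxon set: the frequency of
#' every non-trivial bipartition in every sample, with across-sample mean and
#' standard deviation (sample SD, n-1 denominator).  A split absent from a
#' sample has frequency 0 there.
#'
#' @slot taxa Character vector, the common taxon set.
#' @slot freq Numeric matrix, rows = splits, columns = samples.
#' @slot splits List of character vectors: the canonical side of each
#'   bipartition (the side not containing the lexicographically smallest
#'   taxon).
#' @seealso [splitFrequencyTable()], [asdsf()], [flagUnstableSplits()]
#' @export
setClass("SplitFrequencyTable",
    representation(taxa = "character", freq = "matrix", splits = "list"))

setValidity("SplitFrequencyTable", function(object) {
    f <- object@freq
    if (nrow(f) != length(object@splits))
        return("one frequency row per split required")
    if (length(f) && (any(f < 0) || any(f > 1)))
        return("frequencies must lie in [0, 1]")
    small <- sort(object@taxa)[1L]
    for (s in object@splits) {
        if (!length(s) || length(s) >= length(object@taxa))
            return("split sides must be proper non-empty subsets")
        if (small %in% s)
            return("canonical split side must not contain the smallest taxon")
        if (!all(s %in% object@taxa))
            return("split side contains unknown taxa")
    }
    TRUE
})

#' Rogue-taxon search report
#'
#' Ordered list of accepted dropsets from the greedy dropset search, each with
#' its raw improvement (sum of increases in majority-rule consensus support,
#' in support units), relative improvement (raw / pre-drop total support, a
#' package convention), and consensus resolution before/after removal.
#'
#' @slot dropsets List of character vectors (taxa removed per iteration).
#' @slot rawImprovement Numeric vector, one value per accepted dropset.
#' @slot relativeImprovement Numeric vector.
#' @slot resolutionBefore,resolutionAfter Numeric vectors (percent).
#' @slot settings Named list: maxDropsetSize, threshold, minRawImprovement.
#' @seealso [findRogues()], [supportGain()]
#' @export
setClass("RogueReport",
    representation(dropsets = "list", rawImprovement = "numeric",
                   relativeImprovement = "numeric",
                   resolutionBefore = "numeric", resolutionAfter = "numeric",
                   settings = "list"))

setValidity("RogueReport", function(object) {
    k <- length(object@dropsets)
    if (length(object@rawImprovement) != k ||
        length(object@relativeImprovement) != k)
        return("one improvement value per dropset required")
    if (k > 1L) {
        all_taxa <- unlist(object@dropsets)
        if (anyDuplicated(all_taxa)) return("accepted dropsets must be disjoint")
        if (is.unsorted(rev(object@rawImprovement)))
            return("dropsets must be in descending order of raw improvement")
    }
    TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "Alignment", function(object) {
    cat("Alignment:", nrow(object@seqs), "taxa x", ncol(object@seqs),
        "columns\n")
    if (length(object@partitions))
        cat("  partitions:", paste(names(object@partitions), collapse = ", "),
            "\n")
})

setMethod("show", "TreeSample", function(object) {
    cat("TreeSample:", length(object@trees), "trees over",
        length(object@taxa), "taxa")
    if (nzchar(object@origin)) cat(" (", object@origin, ")", sep = "")
    cat("\n")
})

setMethod("show", "PresenceMatrix", function(object) {
    cat("PresenceMatrix:", nrow(object@present), "taxa x",
        ncol(object@present), "genes;",
        sprintf("%.1f%% present\n", 100 * mean(object@present)))
})

setMethod("show", "SplitFrequencyTable", function(object) {
    cat("SplitFrequencyTable:", nrow(object@freq), "splits x",
        ncol(object@freq), "samples over", length(object@taxa), "taxa\n")
})

setMethod("show", "RogueReport", function(object) {
    k <- length(object@dropsets)
    cat("RogueReport:", k, "accepted dropset(s)\n")
    if (k) {
        for (i in seq_len(k))
            cat(sprintf("  %d. {%s}  raw improvement %.3f\n", i,
                        paste(object@dropsets[[i]], collapse = ", "),
                        object@rawImprovement[i]))
    }
})

## ---- generics and accessors -------------------------------------------------

#' Taxon labels of an object
#' @param x An `Alignment`, `TreeSample`, `PresenceMatrix` or
#'   `SplitFrequencyTable`.
#' @return Character vector of taxon labels.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname taxa
#' @export
setMethod("taxa", "Alignment", function(x) rownames(x@seqs))
#' @rdname taxa
#' @export
setMethod("taxa", "TreeSample", function(x) x@taxa)
#' @rdname taxa
#' @export
setMethod("taxa", "PresenceMatrix", function(x) rownames(x@present))
#' @rdname taxa
#' @export
setMethod("taxa", "SplitFrequencyTable", function(x) x@taxa)

#' Number of alignment columns
#' @param x An `Alignment`.
#' @return Integer number of columns (sites).
#' @export
alignmentColumns <- function(x) {
    stopifnot(is(x, "Alignment"))
    ncol(x@seqs)
}

#' Sequence matrix of an alignment
#' @param x An `Alignment`.
#' @return The taxon-by-column character matrix.
#' @export
alignmentMatrix <- function(x) {
    stopifnot(is(x, "Alignment"))
    x@seqs
}

#' Named partitions of an alignment
#' @param x An `Alignment`.
#' @return Named list of 1-based column index vectors.
#' @export
alignmentPartitions <- function(x) {
    stopifnot(is(x, "Alignment"))
    x@partitions
}

#' Trees held by a TreeSample
#' @param x A `TreeSample`.
#' @return A `multiPhylo` object.
#' @export
sampleTrees <- function(x) {
    stopifnot(is(x, "TreeSample"))
    x@trees
}

#' Number of trees in a TreeSample
#' @param x A `TreeSample`.
#' @return Integer count.
#' @export
sampleSize <- function(x) {
    stopifnot(is(x, "TreeSample"))
    length(x@trees)
}

#' Presence matrix of a PresenceMatrix object
#' @param x A `PresenceMatrix`.
#' @return Logical taxon-by-gene matrix.
#' @export
presenceValues <- function(x) {
    stopifnot(is(x, "PresenceMatrix"))
    x@present
}

#' Taxon annotation table of a PresenceMatrix
#' @param x A `PresenceMatrix`.
#' @return data.frame with taxon, group and any family/superfamily tags.
#' @export
taxonTable <- function(x) {
    stopifnot(is(x, "PresenceMatrix"))
    x@taxa
}

#' Split frequencies as a matrix
#' @param x A `SplitFrequencyTable`.
#' @return Numeric matrix, rows = splits, columns = samples; row names are the
#'   canonical split sides collapsed with `|`.
#' @export
splitFrequencies <- function(x) {
    stopifnot(is(x, "SplitFrequencyTable"))
    f <- x@freq
    rownames(f) <- vapply(x@splits, paste, "", collapse = "|")
    f
}

#' Canonical split sides of a SplitFrequencyTable
#' @param x A `SplitFrequencyTable`.
#' @return List of character vectors.
#' @export
splitSides <- function(x) {
    stopifnot(is(x, "SplitFrequencyTable"))
    x@splits
}

#' Accepted dropsets of a RogueReport
#' @param x A `RogueReport`.
#' @return List of character vectors.
#' @export
rogueDropsets <- function(x) {
    stopifnot(is(x, "RogueReport"))
    x@dropsets
}

#' Tabular view of a RogueReport
#' @param x A `RogueReport`.
#' @return data.frame with rank, taxa (comma-separated), raw and relative
#'   improvement, and resolution before/after.
#' @export
rogueTable <- function(x) {
    stopifnot(is(x, "RogueReport"))
    k <- length(x@dropsets)
    data.frame(
        rank = seq_len(k),
        taxa = vapply(x@dropsets, paste, "", collapse = ","),
        raw_improvement = x@rawImprovement,
        relative_improvement = x@relativeImprovement,
        resolution_before = x@resolutionBefore,
        resolution_after = x@resolutionAfter,
        stringsAsFactors = FALSE)
}
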