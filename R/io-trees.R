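#' Construct a TreeSample from trees
#'
#' @param trees A `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @param origin Free-text provenance.
#' @param allowHeterogeneous If `FALSE` (default) all trees must share one
#'   leaf set; if `TRUE` the taxon set is the union and the sample must be
#'   restricted (see [restrictSample()]) before split statistics.
#' @return A [TreeSample-class] object.
#' @export
treeSample <- function(trees, origin = "", allowHeterogeneous = FALSE) {
    if (inherits(trees, "phylo")) trees <- list(trees)
    if (inherits(trees, "multiPhylo") && !is.null(attr(trees, "TipLabel")))
        trees <- ape::.uncompressTipLabel(trees)  # resolved translate table
    trees <- unclass(trees)
    attr(trees, "TipLabel") <- NULL
    stopifnot(length(trees) >= 1L)
    lapply(trees, function(t) {
        if (!inherits(t, "phylo")) stop("all elements must be phylo trees")
    })
    sets <- lapply(trees, function(t) sort(t$tip.label))
    if (!allowHeterogeneous && length(trees) > 1L) {
        if (!all(vapply(sets[-1L], identical, TRUE, sets[[1L]])))
            stop("trees have differing leaf sets; pass allowHeterogeneous ",
                 "= TRUE and restrict to shared taxa before split statistics")
    }
    class(trees) <- "multiPhylo"
    new("TreeSample", trees = trees,
        taxa = sort(unique(unlist(sets))), origin = origin)
}

#' Read a tree sample from file
#'
#' Two dialects are supported: a plain list of Newick strings (one tree per
#' line or `;`-separated) and a NEXUS TREES block, whose translate table is
#' resolved to full labels.  The file is only interpreted under the named
#' dialect.
#'
#' @param path File path.
#' @param format `"newick_list"` or `"nexus_trees"`.
#' @inheritParams treeSample
#' @return A [TreeSample-class] object.
#' @export
readTreeSample <- function(path, format = c("newick_list", "nexus_trees"),
                           allowHeterogeneous = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "nexus_trees") {
        first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
        if (!startsWith(first, "#NEXUS"))
            stop("not a NEXUS file: ", path)
        trs <- ape::read.nexus(path)
    } else {
        first <- trimws(readLines(path, n = 1L, warn = FALSE))
        if (startsWith(toupper(first), "#NEXUS"))
            stop("file looks like NEXUS; use format = \"nexus_trees\"")
        trs <- ape::read.tree(path)
    }
    if (is.null(trs)) stop("no parseable tree in ", path)
    treeSample(trs, origin = basename(path),
               allowHeterogeneous = allowHeterogeneous)
}

#' Serialise a tree as Newick
#'
#' @param tree A `phylo` object, optionally with support values in
#'   `$node.label`.
#' @param withSupport Emit internal node labels (support values) if present.
#' @param path Optional file path; when given the string is also written there.
#' @return The Newick string, invisibly when `path` is given.  Output
#'   re-parses to a tree with identical splits and branch lengths (to 1e-9).
#' @export
writeTree <- function(tree, withSupport = TRUE, path = NULL) {
    stopifnot(inherits(tree, "phylo"))
    t2 <- tree
    if (!withSupport) t2$node.label <- NULL
    s <- ape::write.tree(t2, digits = 12)
    if (!is.null(path)) {
        writeLines(s, path)
        return(invisible(s))
    }
    s
}

#' Write a tree sample as a Newick list
#'
#' @param sample A [TreeSample-class].
#' @param path Output file path (one Newick string per line).
#' @return `path`, invisibly.
#' @export
writeTreeSample <- function(sample, path) {
    stopifnot(is(sample, "TreeSample"))
    writeLines(vapply(sample@trees, function(t) ape::write.tree(t, digits = 12),
                      ""), path)
    invisible(path)
}
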