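## Workflow layer: one configuration in, the study-style assessment tables
## out (data properties, saturation, congruence matrix, rogue report,
## coverage census), with a machine-readable manifest for reproducibility.

.as_alignment <- function(x) {
    if (is(x, "Alignment")) return(x)
    if (is.character(x) && length(x) == 1L) {
        fmt <- switch(tolower(tools::file_ext(x)),
                      nex = , nexus = "nexus",
                      phy = , phylip = "phylip",
                      "fasta")
        return(readAlignment(x, fmt))
    }
    stop("cannot interpret alignment input")
}

.as_tree <- function(x) {
    if (inherits(x, "phylo")) return(x)
    if (is.character(x) && length(x) == 1L && file.exists(x))
        return(ape::read.tree(x))
    stop("cannot interpret tree input")
}

.as_sample <- function(x) {
    if (is(x, "TreeSample")) return(x)
    if (is.character(x) && length(x) == 1L && file.exists(x))
        return(readTreeSample(x, "newick_list"))
    stop("cannot interpret tree-sample input")
}

## OLS slope through the origin on (patristic, p-distance) pairs: a scalar
## summary of the saturation plot (a package convention; saturation shows as
## slopes well below 1 and plateauing p-distances).
.saturation <- function(aln, tree) {
    pd <- pDistanceMatrix(aln)
    pat <- patristicMatrix(tree)
    shared <- intersect(rownames(pd$d), rownames(pat$d))
    if (length(shared) < 2L) stop("alignment and tree share < 2 taxa")
    x <- pat$d[shared, shared][lower.tri(diag(length(shared)))]
    y <- pd$d[shared, shared][lower.tri(diag(length(shared)))]
    ok <- !is.na(x) & !is.na(y)
    list(pairs = data.frame(patristic = x[ok], p_distance = y[ok]),
         slope = sum(x[ok] * y[ok]) / sum(x[ok]^2))
}

#' Per-partition data-property report
#'
#' One row per partition with alignment length, variable and
#' parsimony-informative site counts, pooled GC percent and the stationarity
#' chi-square test; plus, for partitions supplying a best tree, the
#' saturation pairs (p-distance vs patristic distance) and their
#' through-origin regression slope.
#'
#' @param config List with element `partitions`: a named list, each entry a
#'   list with `alignment` (an [Alignment-class] or file path) and optional
#'   `tree` (a `phylo` or Newick path).
#' @return List with `table` (data.frame) and `saturation` (named list of
#'   `pairs`/`slope`, one entry per partition with a tree).
#' @export
runDataProperties <- function(config) {
    stopifnot(is.list(config$partitions), length(config$partitions) >= 1L)
    parts <- config$partitions
    rows <- list(); satur <- list()
    for (nm in names(parts)) {
        aln <- .as_alignment(parts[[nm]]$alignment)
        sc <- classifySites(aln)
        bc <- baseComposition(aln)
        st <- stationarityChi2(aln)
        rows[[nm]] <- data.frame(
            partition = nm, n_bp = sc$n_sites, n_var = sc$variable,
            n_pars = sc$parsimony_informative,
            gc_pct = 100 * bc$gc_pooled,
            chi_square = st$chi_square, df = st$df, p_value = st$p_value,
            stringsAsFactors = FALSE)
        if (!is.null(parts[[nm]]$tree)) {
            tr <- .as_tree(parts[[nm]]$tree)
            if (!all(rownames(aln@seqs) %in% tr$tip.label))
                stop("partition '", nm, "': tree is missing alignment taxa")
            satur[[nm]] <- .saturation(aln, tr)
        }
    }
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         saturation = satur)
}

#' Congruence matrix between tree samples
#'
#' Restricts every sample to the shared taxon set (explicit list or
#' auto-intersection), then reports per-partition consensus resolution and
#' the pairwise ASDSF against each reference sample.
#'
#' @param config List with `samples` (named list of [TreeSample-class] or
#'   Newick-list paths), optional `references` (same, defaults to `samples`),
#'   optional `restrict` (taxon vector; default: intersection of all leaf
#'   sets), `minFreq` (default 0.10) and `threshold` (default 0.5).
#' @return List with `table` (data.frame: partition, resolution_pct, one
#'   ASDSF column per reference) and `shared_taxa`.
#' @export
runCongruenceMatrix <- function(config) {
    samples <- lapply(config$samples, .as_sample)
    stopifnot(length(samples) >= 1L)
    refs <- if (is.null(config$references)) samples
            else lapply(config$references, .as_sample)
    minFreq <- if (is.null(config$minFreq)) 0.10 else config$minFreq
    threshold <- if (is.null(config$threshold)) 0.5 else config$threshold
    shared <- config$restrict
    if (is.null(shared)) {
        shared <- Reduce(intersect, lapply(c(samples, refs), taxa))
    }
    if (length(shared) < 4L) stop("shared taxon set has fewer than 4 taxa")
    samples <- lapply(samples, restrictSample, taxa = shared)
    refs <- lapply(refs, restrictSample, taxa = shared)
    rows <- lapply(names(samples), function(nm) {
        cons <- majorityConsensus(samples[[nm]], threshold)
        row <- data.frame(partition = nm,
                          resolution_pct = resolutionPercent(cons),
                          stringsAsFactors = FALSE)
        for (rn in names(refs)) {
            row[[paste0("asdsf_", rn)]] <-
                asdsf(list(samples[[nm]], refs[[rn]]), minFreq)$asdsf
        }
        row
    })
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         shared_taxa = sort(shared))
}

#' Full assessment pipeline
#'
#' Runs the data-property, congruence, rogue and coverage stages on one
#' configuration and writes TSV/JSON reports plus a manifest (inputs,
#' settings, versions, seed) to `config$outdir`.  Reruns with an identical
#' configuration produce byte-identical files.
#'
#' @param config List combining the [runDataProperties()] and
#'   [runCongruenceMatrix()] inputs with: `presence` (a
#'   [PresenceMatrix-class] or TSV path, optional), `outdir` (required),
#'   `seed` (recorded in the manifest), `burninFraction` (default 0.25),
#'   `rogue` (list: `maxDropsetSizes` default `c(2, 3, 10)`,
#'   `minRawImprovement` default 0.5).
#' @return Invisibly, a list with all stage results plus `manifest`.
#' @export
runFull <- function(config) {
    stopifnot(!is.null(config$outdir))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outdir, f)
    burnin <- if (is.null(config$burninFraction)) 0.25
              else config$burninFraction
    rg <- config$rogue
    if (is.null(rg)) rg <- list()
    if (is.null(rg$maxDropsetSizes)) rg$maxDropsetSizes <- c(2, 3, 10)
    if (is.null(rg$minRawImprovement)) rg$minRawImprovement <- 0.5
    threshold <- if (is.null(config$threshold)) 0.5 else config$threshold

    results <- list()

    dp <- runDataProperties(config)
    .write_tsv(dp$table, out("data_properties.tsv"))
    results$data_properties <- dp

    samples <- lapply(config$samples, .as_sample)
    samples <- lapply(samples, subsampleTrees, burninFraction = burnin)
    cm_config <- config
    cm_config$samples <- samples
    cm <- runCongruenceMatrix(cm_config)
    .write_tsv(cm$table, out("congruence.tsv"))
    results$congruence <- cm

    rogue_runs <- lapply(samples, function(s) {
        reports <- lapply(rg$maxDropsetSizes, function(k)
            findRogues(s, maxDropsetSize = k, threshold = threshold,
                       minRawImprovement = rg$minRawImprovement))
        taxa_sets <- lapply(reports, function(r) sort(unlist(r@dropsets)))
        list(report = reports[[length(reports)]],
             agreement = all(vapply(taxa_sets, identical, TRUE,
                                    taxa_sets[[1L]])))
    })
    rogue_tab <- do.call(rbind, c(lapply(names(rogue_runs), function(nm) {
        tb <- rogueTable(rogue_runs[[nm]]$report)
        if (nrow(tb)) cbind(partition = nm, tb,
                            dropset_size_agreement =
                                rogue_runs[[nm]]$agreement)
        else NULL
    }), list(make.row.names = FALSE)))
    if (is.null(rogue_tab))
        rogue_tab <- data.frame(partition = character(0))
    .write_tsv(rogue_tab, out("rogues.tsv"))
    results$rogues <- rogue_runs

    ## Consensus trees, with identified rogues flagged (the tree-figure
    ## convention of dashing rogue branches, as a machine-readable list).
    cons_annot <- list()
    for (nm in names(samples)) {
        cons <- majorityConsensus(samples[[nm]], threshold)
        writeTree(cons, path = out(paste0("consensus_", nm, ".nwk")))
        cons_annot[[nm]] <- list(
            rogue_taxa = sort(unlist(
                rogue_runs[[nm]]$report@dropsets)) %||% character(0))
    }
    jsonlite::write_json(cons_annot, out("consensus_annotations.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    if (!is.null(config$presence)) {
        pm <- if (is(config$presence, "PresenceMatrix")) config$presence
              else readPresenceMatrix(config$presence)
        cov <- coverageStats(pm)
        cen <- taxonCensus(pm)
        jsonlite::write_json(
            list(coverage = cov[c("overall_pct", "overall_pct_rounded",
                                  "per_gene_pct", "per_gene_pct_rounded",
                                  "mean_genes_per_taxon")],
                 census = cen),
            out("coverage.json"), auto_unbox = TRUE, pretty = TRUE,
            digits = NA)
        results$coverage <- cov
        results$census <- cen
    }

    files <- sort(setdiff(list.files(config$outdir), "manifest.json"))
    manifest <- list(
        package = "PhyloCongruence",
        version = as.character(utils::packageVersion("PhyloCongruence")),
        seed = config$seed,
        settings = list(burninFraction = burnin, threshold = threshold,
                        minFreq = if (is.null(config$minFreq)) 0.10
                                  else config$minFreq,
                        rogue = rg),
        outputs = as.list(tools::md5sum(file.path(config$outdir, files))))
    names(manifest$outputs) <- files
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    results$manifest <- manifest
    invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Default synthetic input bundle
#'
#' Builds a fully synthetic configuration for [runFull()]: a true tree, two
#' partition alignments simulated under GTR+G+I at contrasting rates, two
#' NNI-perturbed pseudo-posterior samples (one with an injected rogue), and a
#' sparse presence matrix.  Everything derives deterministically from `seed`.
#'
#' @param seed Integer seed.
#' @param outdir Output directory stored in the config.
#' @param nTaxa,nTrees,sites Problem sizes.
#' @return A config list for [runFull()].
#' @export
syntheticBundle <- function(seed = 1, outdir = tempfile("bundle"),
                            nTaxa = 12, nTrees = 80, sites = 300) {
    tree <- simTree(nTaxa, seed = seed)
    scale_tree <- function(t, f) { t$edge.length <- t$edge.length * f; t }
    aln_slow <- simAlignment(tree, simulationParams(
        length = sites, rateMultiplier = 0.5, seed = seed + 1L))
    aln_fast <- simAlignment(tree, simulationParams(
        length = sites, rateMultiplier = 4, seed = seed + 2L))
    s1 <- simTreeSample(tree, nTrees, nniMoves = 1, seed = seed + 3L)
    s2 <- simTreeSample(tree, nTrees, nniMoves = 1,
                        rogues = tree$tip.label[1L], seed = seed + 4L)
    pm <- simPresenceMatrix(30, 7, 0.84, seed = seed + 5L, nOutgroup = 6)
    ## each partition pairs with the tree at its own rate scale, mimicking a
    ## branch-length estimate from that partition alone
    list(partitions = list(
             slow = list(alignment = aln_slow, tree = scale_tree(tree, 0.5)),
             fast = list(alignment = aln_fast, tree = scale_tree(tree, 4))),
         samples = list(run1 = s1, run2 = s2),
         presence = pm, outdir = outdir, seed = seed,
         burninFraction = 0.25)
}
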