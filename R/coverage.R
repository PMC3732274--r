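#' Gene-coverage statistics of a presence matrix
#'
#' Overall coverage is `100 * present cells / (taxa * genes)`; per-gene
#' coverage is the percentage of taxa with that gene present.  Percentages
#' are reported raw and rounded to the nearest integer percent, and
#' recomputed within each declared group tag (e.g. coverage of a gene within
#' the ingroup only).
#'
#' @param pm A [PresenceMatrix-class].
#' @return List with `overall_pct`, `overall_pct_rounded`, `per_gene_pct`,
#'   `per_gene_pct_rounded` (named vectors), `mean_genes_per_taxon`,
#'   `per_taxon_missing` (named integer vector of missing-gene counts), and
#'   `group_pct` (list per group tag with `overall_pct` and `per_gene_pct`).
#' @export
coverageStats <- function(pm) {
    stopifnot(is(pm, "PresenceMatrix"))
    m <- pm@present
    if (!length(m)) stop("empty presence matrix")
    per_gene <- 100 * colMeans(m)
    out <- list(
        overall_pct = 100 * mean(m),
        overall_pct_rounded = round(100 * mean(m)),
        per_gene_pct = per_gene,
        per_gene_pct_rounded = round(per_gene),
        mean_genes_per_taxon = mean(rowSums(m)),
        per_taxon_missing = stats::setNames(ncol(m) - rowSums(m), rownames(m)))
    groups <- unique(pm@taxa$group)
    out$group_pct <- lapply(stats::setNames(groups, groups), function(g) {
        mg <- m[pm@taxa$group == g, , drop = FALSE]
        list(overall_pct = 100 * mean(mg),
             per_gene_pct = 100 * colMeans(mg))
    })
    out
}

#' Taxon sampling census
#'
#' Counts ingroup species rows, outgroup rows, and the distinct family and
#' superfamily tags among ingroup rows.
#'
#' @param pm A [PresenceMatrix-class] whose taxon table carries `family` and
#'   `superfamily` columns.
#' @return List with `ingroup_species`, `outgroup_taxa`, `families`,
#'   `superfamilies`.
#' @export
taxonCensus <- function(pm) {
    stopifnot(is(pm, "PresenceMatrix"))
    tt <- pm@taxa
    if (!all(c("family", "superfamily") %in% colnames(tt)))
        stop("taxon table needs 'family' and 'superfamily' tag columns")
    ing <- tt[tt$group == "ingroup", , drop = FALSE]
    n_distinct <- function(x) length(unique(x[!is.na(x) & nzchar(x)]))
    list(ingroup_species = nrow(ing),
         outgroup_taxa = sum(tt$group == "outgroup"),
         families = n_distinct(ing$family),
         superfamilies = n_distinct(ing$superfamily))
}
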