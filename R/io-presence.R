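#' Read a taxon-by-gene presence matrix from TSV
#'
#' The file needs a header row naming the columns.  Tag columns (any of
#' `taxon`, `group`, `family`, `superfamily`) come first; every remaining
#' column is a gene.  A cell is absent when it is empty, `0`, `missing` or
#' `(missing)` (case-insensitive); anything else (an accession number, `1`,
#' `x`) is present.
#'
#' @param path TSV file path.
#' @return A [PresenceMatrix-class] object.
#' @examples
#' f <- system.file("extdata", "table1_presence.tsv",
#'                  package = "PhyloCongruence")
#' pm <- readPresenceMatrix(f)
#' coverageStats(pm)$overall_pct
#' @export
readPresenceMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
    if (length(unique(nf)) > 1L) {
        bad <- which(nf != nf[1L])[1L]
        stop("inconsistent row width at line ", bad, ": ", nf[bad],
             " fields, expected ", nf[1L])
    }
    df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                            comment.char = "", check.names = FALSE)
    tag_cols <- intersect(c("taxon", "group", "family", "superfamily"),
                          colnames(df))
    if (!all(c("taxon", "group") %in% tag_cols))
        stop("presence TSV needs 'taxon' and 'group' columns")
    gene_cols <- setdiff(colnames(df), tag_cols)
    if (!length(gene_cols)) stop("presence TSV has no gene columns")
    if (anyDuplicated(df$taxon))
        stop("duplicate taxon label: ", df$taxon[duplicated(df$taxon)][1L])
    pres <- as.matrix(df[gene_cols])
    absent <- tolower(trimws(pres)) %in% c("", "0", "missing", "(missing)", "na")
    m <- matrix(!absent, nrow(pres), ncol(pres),
                dimnames = list(df$taxon, gene_cols))
    new("PresenceMatrix", present = m,
        taxa = df[c(tag_cols)])
}

#' Construct a PresenceMatrix from a logical matrix
#'
#' @param present Logical taxon-by-gene matrix (rownames, colnames required).
#' @param group Character vector of `"ingroup"`/`"outgroup"` tags, recycled.
#' @param family,superfamily Optional tag vectors.
#' @return A [PresenceMatrix-class] object.
#' @export
presenceMatrix <- function(present, group = "ingroup",
                           family = NULL, superfamily = NULL) {
    df <- data.frame(taxon = rownames(present),
                     group = rep_len(group, nrow(present)),
                     stringsAsFactors = FALSE)
    if (!is.null(family)) df$family <- rep_len(family, nrow(present))
    if (!is.null(superfamily))
        df$superfamily <- rep_len(superfamily, nrow(present))
    new("PresenceMatrix", present = present, taxa = df)
}
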