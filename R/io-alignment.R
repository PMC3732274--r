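#' Construct an Alignment from named sequences
#'
#' @param seqs Named character vector of sequence strings, or a character
#'   matrix with taxon rownames (one column per site).
#' @param partitions Optional named list of 1-based column index vectors.
#' @return An [Alignment-class] object.  `U` is normalised to `T` and input is
#'   upper-cased; ragged, duplicated-taxon or unknown-symbol input errors.
#' @examples
#' aln <- alignment(c(t1 = "ACGT", t2 = "AC-T"))
#' alignmentColumns(aln)
#' @export
alignment <- function(seqs, partitions = list()) {
    if (is.matrix(seqs)) {
        m <- seqs
    } else {
        if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
            stop("sequences must be named by taxon")
        lens <- nchar(seqs)
        if (length(unique(lens)) > 1L) {
            off <- names(seqs)[lens != lens[1L]][1L]
            stop("ragged alignment: taxon '", off, "' has length ",
                 nchar(seqs[[off]]), ", expected ", lens[1L])
        }
        m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
        rownames(m) <- names(seqs)
    }
    m[] <- toupper(m)
    m[m == "U"] <- "T"
    m[m == "."] <- "-"
    bad <- setdiff(unique(as.vector(m)), .DNA_ALPHABET)
    if (length(bad)) {
        col <- which(matrix(m %in% bad, nrow(m)), arr.ind = TRUE)[1L, ]
        stop("unknown symbol '", m[col[1L], col[2L]], "' at column ",
             col[2L], " (taxon '", rownames(m)[col[1L]], "')")
    }
    partitions <- lapply(partitions, function(i) sort(as.integer(i)))
    new("Alignment", seqs = m, partitions = partitions)
}

#' Read a nucleotide alignment from file
#'
#' Supports aligned FASTA, NEXUS (DATA/CHARACTERS block) and relaxed PHYLIP
#' (header line `ntax nchar`, then whitespace-separated `name sequence`
#' records, sequences possibly wrapped over several lines).  Parsing is
#' dialect-strict: a file is only interpreted under the named format.
#'
#' @param path File path.
#' @param format One of `"fasta"`, `"nexus"`, `"phylip"`.
#' @param partitions Optional named list of column index vectors attached to
#'   the result.
#' @return An [Alignment-class] object.
#' @seealso [writeAlignment()], [alignment()]
#' @export
readAlignment <- function(path, format = c("fasta", "nexus", "phylip"),
                          partitions = list()) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    seqs <- switch(format,
        fasta  = .read_fasta(path),
        nexus  = .read_nexus_aln(path),
        phylip = .read_relaxed_phylip(path))
    alignment(seqs, partitions = partitions)
}

.read_fasta <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("not a FASTA file (no '>' headers): ", path)
    if (hdr[1L] != 1L) stop("FASTA parse error: text before first header")
    nm <- trimws(sub("^>\\s*", "", lines[hdr]))
    nm <- vapply(strsplit(nm, "\\s+"), `[`, "", 1L)
    starts <- hdr + 1L
    ends <- c(hdr[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
        if (starts[i] > ends[i]) return("")
        paste(gsub("\\s", "", lines[starts[i]:ends[i]]), collapse = "")
    }, "")
    names(seqs) <- nm
    if (anyDuplicated(nm))
        stop("duplicate taxon label: ", nm[duplicated(nm)][1L])
    seqs
}

.read_nexus_aln <- function(path) {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    if (!startsWith(first, "#NEXUS")) stop("not a NEXUS file: ", path)
    x <- ape::read.nexus.data(path)
    other <- .nexus_other_blocks(path, keep = c("DATA", "CHARACTERS", "TAXA"))
    if (length(other))
        warning("ignoring NEXUS block(s): ", paste(other, collapse = ", "))
    vapply(x, function(s) paste(s, collapse = ""), "")
}

.nexus_other_blocks <- function(path, keep) {
    lines <- toupper(readLines(path, warn = FALSE))
    m <- regmatches(lines, regexpr("BEGIN\\s+[A-Z]+", lines))
    blocks <- unique(sub("BEGIN\\s+", "", unlist(m)))
    setdiff(blocks, keep)
}

## Relaxed PHYLIP: names are whitespace-delimited tokens of any length.
.read_relaxed_phylip <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
        stop("not a PHYLIP file (expected 'ntax nchar' header): ", path)
    ntax <- as.integer(hdr[1L]); nchar_exp <- as.integer(hdr[2L])
    body <- lines[-1L]
    seqs <- character(0)
    i <- 1L
    for (k in seq_len(ntax)) {
        if (i > length(body)) stop("PHYLIP parse error: only ", k - 1L,
                                   " of ", ntax, " records found")
        toks <- strsplit(trimws(body[i]), "\\s+")[[1L]]
        nm <- toks[1L]
        s <- paste(toks[-1L], collapse = "")
        i <- i + 1L
        while (nchar(s) < nchar_exp && i <= length(body)) {
            s <- paste0(s, gsub("\\s", "", body[i]))
            i <- i + 1L
        }
        if (nchar(s) != nchar_exp)
            stop("ragged PHYLIP record for taxon '", nm, "': got ",
                 nchar(s), " characters, expected ", nchar_exp)
        seqs[nm] <- s
    }
    if (anyDuplicated(names(seqs)))
        stop("duplicate taxon label: ", names(seqs)[duplicated(names(seqs))][1L])
    seqs
}

#' Write an alignment to file
#'
#' @param aln An [Alignment-class] object.
#' @param path Output file path.
#' @param format One of `"fasta"`, `"nexus"`, `"phylip"`.
#' @return `path`, invisibly.  Writers are deterministic: re-reading yields an
#'   identical alignment cell-for-cell.
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "nexus", "phylip")) {
    format <- match.arg(format)
    stopifnot(is(aln, "Alignment"))
    m <- aln@seqs
    strs <- apply(m, 1L, paste, collapse = "")
    con <- file(path, "w")
    on.exit(close(con))
    if (format == "fasta") {
        for (nm in rownames(m))
            writeLines(c(paste0(">", nm), strs[[nm]]), con)
    } else if (format == "phylip") {
        writeLines(paste(nrow(m), ncol(m)), con)
        for (nm in rownames(m)) writeLines(paste(nm, strs[[nm]]), con)
    } else {
        writeLines(c("#NEXUS", "BEGIN DATA;",
                     paste0("  DIMENSIONS NTAX=", nrow(m),
                            " NCHAR=", ncol(m), ";"),
                     "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
                     "  MATRIX"), con)
        for (nm in rownames(m)) writeLines(paste0("    ", nm, "  ", strs[[nm]]), con)
        writeLines(c("  ;", "END;"), con)
    }
    invisible(path)
}
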