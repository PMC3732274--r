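#' Extract alignment anchor constraints from stem regions
#'
#' Scans a stem-annotated reference alignment for length-constant stem
#' regions: maximal runs of mask-true columns in which every taxon has a
#' non-gap state (`-` and `?` break the run; ambiguity codes count as
#' states).  Runs of at least `minLen` columns qualify, and each contributes
#' one anchor: its most conserved column (highest modal-base fraction over
#' taxa), ties broken by proximity to the run's midpoint (even-length runs
#' resolve to the lower-middle column), then by lower column index.
#'
#' @param refAln An [Alignment-class] (the reference alignment).
#' @param stemMask Logical vector, one value per alignment column, `TRUE`
#'   inside annotated stem regions.
#' @param minLen Minimum qualifying run length in columns (default 10).
#' @return data.frame with 1-based columns `stem_start`, `stem_end`,
#'   `anchor_col`, `conservation`; attribute `min_len` records the setting.
#' @export
extractConstraints <- function(refAln, stemMask, minLen = 10) {
    stopifnot(is(refAln, "Alignment"))
    m <- refAln@seqs
    stemMask <- as.logical(stemMask)
    if (length(stemMask) != ncol(m))
        stop("stem mask length ", length(stemMask),
             " does not match alignment columns ", ncol(m))
    gap_free <- colSums(matrix(m %in% .DNA_GAPS, nrow(m))) == 0L
    ok <- stemMask & gap_free
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- data.frame(stem_start = integer(0), stem_end = integer(0),
                      anchor_col = integer(0), conservation = numeric(0))
    for (k in which(r$values & r$lengths >= minLen)) {
        s <- starts[k]; e <- ends[k]; L <- e - s + 1L
        cons <- vapply(s:e, function(j) {
            tab <- table(m[, j][m[, j] %in% .DNA_BASES])
            if (!length(tab)) 0 else max(tab) / nrow(m)
        }, 0)
        mid <- s + ceiling(L / 2) - 1L   # even length -> lower-middle
        cols <- s:e
        ord <- order(-cons, abs(cols - mid), cols)
        a <- cols[ord[1L]]
        out <- rbind(out, data.frame(stem_start = s, stem_end = e,
                                     anchor_col = a,
                                     conservation = cons[ord[1L]]))
    }
    rownames(out) <- NULL
    attr(out, "min_len") <- minLen
    out
}
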