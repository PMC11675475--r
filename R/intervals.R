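#' Pairs of overlapping intervals between two sorted collections
#'
#' Returns every (a, b) index pair sharing at least `minOverlap` bp on the
#' same chromosome. Strand is ignored, matching peak-set semantics.
#'
#' @param a,b GRanges, each sorted by (chromosome, start).
#' @param minOverlap Minimal shared bp (>= 1).
#' @return data.frame with integer columns `a` and `b`.
#' @export
intersectIntervals <- function(a, b, minOverlap = 1L) {
    stopifnot(minOverlap >= 1)
    checkSorted(a, "a")
    checkSorted(b, "b")
    ## disjoint seqlevels between a and b are a legitimate no-overlap case
    hits <- suppressWarnings(
        findOverlaps(a, b, minoverlap = as.integer(minOverlap),
                     ignore.strand = TRUE))
    data.frame(a = queryHits(hits), b = subjectHits(hits))
}

checkSorted <- function(x, label) {
    if (length(x) < 2) return(invisible(TRUE))
    o <- order(as.character(seqnames(x)), start(x))
    if (!identical(o, seq_along(x)))
        stop("interval collection '", label,
             "' must be sorted by (chromosome, start)")
    invisible(TRUE)
}

#' Merge overlapping or near-adjacent intervals
#'
#' Overlapping intervals, and intervals separated by at most `maxGap` bp, are
#' unioned. Bookended intervals (zero bases between them) merge at
#' `maxGap = 0`, matching the common merge-tool default.
#'
#' @param x Sorted GRanges.
#' @param maxGap Maximal separating gap in bp (default 0).
#' @return Sorted, pairwise-disjoint GRanges.
#' @export
mergeIntervals <- function(x, maxGap = 0L) {
    checkSorted(x, "x")
    reduce(x, min.gapwidth = as.integer(maxGap) + 1L, ignore.strand = TRUE)
}

#' Fraction of the genome covered by a peak set
#'
#' Total covered bp (after merging) divided by total genome bp.
#'
#' @param acrs GRanges of ACRs.
#' @param chromSizes Named vector of chromosome lengths (bp).
#' @return Numeric proportion in \[0, 1\].
#' @export
genomeFraction <- function(acrs, chromSizes) {
    if (!length(acrs)) return(0)
    covered <- sum(as.numeric(width(reduce(acrs, ignore.strand = TRUE))))
    covered / sum(as.numeric(chromSizes))
}
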