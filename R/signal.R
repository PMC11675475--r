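#' Genome-wide binned fragment signal in RPM
#'
#' Tiles every chromosome with fixed-width bins and assigns each fragment to
#' the bin containing its midpoint. RPM = 1e6 x bin count / total in-bounds
#' fragments. Fragments whose midpoint falls outside the chromosome bounds
#' are skipped with a counted warning.
#'
#' @param fragments GRanges of fragments (or a BED path).
#' @param chromSizes Named vector of chromosome lengths.
#' @param binWidth Bin width in bp (>= 1; default 1000).
#' @return GRanges of bins with metadata `count` and `rpm`; the total
#'   fragment count is attached as `metadata(x)$totalFragments` via the
#'   `totalFragments` attribute.
#' @export
binnedRPM <- function(fragments, chromSizes, binWidth = 1000) {
    stopifnot(binWidth >= 1)
    if (is.character(fragments)) fragments <- readFragments(fragments)
    bins <- tileChromosomes(chromSizes, binWidth)
    mid <- start(fragments) + (width(fragments) - 1L) %/% 2L
    chrom <- as.character(seqnames(fragments))
    inBounds <- chrom %in% names(chromSizes)
    inBounds[inBounds] <- mid[inBounds] >= 1 &
        mid[inBounds] <= chromSizes[chrom[inBounds]]
    if (any(!inBounds))
        warning(sum(!inBounds), " fragment(s) outside chromosome bounds ",
                "skipped")
    pts <- GRanges(chrom[inBounds], IRanges(mid[inBounds], mid[inBounds]))
    cnt <- countOverlaps(bins, pts)
    total <- sum(cnt)
    bins$count <- cnt
    bins$rpm <- if (total > 0) 1e6 * cnt / total else rep(0, length(bins))
    attr(bins, "totalFragments") <- total
    bins
}

tileChromosomes <- function(chromSizes, binWidth) {
    starts <- lapply(names(chromSizes), function(ch)
        seq.int(1L, as.integer(chromSizes[ch]), by = as.integer(binWidth)))
    chrom <- rep(names(chromSizes), lengths(starts))
    s <- unlist(starts, use.names = FALSE)
    e <- pmin(s + as.integer(binWidth) - 1L,
              as.integer(chromSizes[chrom]))
    GRanges(chrom, IRanges(s, e))
}

#' Pearson correlation between two binned signals
#'
#' @param a,b Binned signals from [binnedRPM()] with identical binning.
#' @param nonzeroOnly Restrict to bins nonzero in either sample
#'   (default FALSE: all bins).
#' @return Pearson r.
#' @export
replicateCorrelation <- function(a, b, nonzeroOnly = FALSE) {
    if (length(a) != length(b) ||
        !all(start(a) == start(b)) ||
        !all(as.character(seqnames(a)) == as.character(seqnames(b))))
        stop("signals must share identical binning")
    x <- a$rpm; y <- b$rpm
    if (nonzeroOnly) {
        keep <- x > 0 | y > 0
        x <- x[keep]; y <- y[keep]
    }
    if (sd(x) == 0 || sd(y) == 0)
        stop("correlation undefined: zero variance in a signal vector")
    cor(x, y)
}

#' TSS/TES metaprofiles stratified by expression level
#'
#' Genes are ranked by expression and split into `nGroups` near-equal groups
#' (ties broken by gene id for determinism; group sizes differ by at most
#' one). For each group the mean fragment RPM is computed in fixed-width
#' bins across \[TSS - window, TSS + window\] and \[TES - window,
#' TES + window\]; minus-strand genes are flipped so negative relative
#' coordinates always mean "upstream".
#'
#' @param fragments GRanges of fragments.
#' @param annotation A GenomeAnnotation.
#' @param expression Named numeric vector of expression values (e.g. stage
#'   mean FPKM); only named genes present in the annotation are used.
#' @param window Half-window in bp (default 2000).
#' @param binWidth Bin width in bp (default 10).
#' @param nGroups Number of expression groups (default 10 = deciles,
#'   group 1 = lowest expression).
#' @return list(tss = , tes = ) of nGroups x nBins matrices of mean RPM,
#'   plus `positions` (bin-center relative coordinates) and `groups`
#'   (named group index per gene).
#' @export
metaProfile <- function(fragments, annotation, expression, window = 2000,
                        binWidth = 10, nGroups = 10) {
    g <- geneModels(annotation)
    ids <- intersect(g$gene_id, names(expression))
    if (length(ids) < nGroups)
        stop("fewer genes than groups")
    g <- g[match(ids, g$gene_id)]
    expr <- expression[ids]
    ord <- order(expr, ids)                    # stable tie-break by gene id
    grp <- integer(length(ids))
    grp[ord] <- ceiling(seq_along(ord) / (length(ord) / nGroups))
    grp[grp > nGroups] <- nGroups
    nBins <- as.integer(2 * window / binWidth)
    rel <- (seq_len(nBins) - 1L) * binWidth - window + binWidth / 2
    mid <- start(fragments) + (width(fragments) - 1L) %/% 2L
    pts <- GRanges(seqnames(fragments), IRanges(mid, mid))
    total <- length(pts)
    plus <- as.character(strand(g)) == "+"
    profileAt <- function(center) {
        binStart <- rep(center, each = nBins) +
            rep(seq_len(nBins) - 1L, length(center)) * binWidth - window
        binGR <- GRanges(rep(as.character(seqnames(g)), each = nBins),
                         IRanges(pmax(binStart, 1L),
                                 pmax(binStart + binWidth - 1L, 1L)))
        cnt <- countOverlaps(binGR, pts)
        m <- matrix(cnt, nrow = nBins)           # bins x genes
        m[, !plus] <- m[rev(seq_len(nBins)), !plus]   # flip minus strand
        rpm <- 1e6 * m / total
        out <- matrix(NA_real_, nrow = nGroups, ncol = nBins,
                      dimnames = list(paste0("group", seq_len(nGroups)),
                                      NULL))
        for (k in seq_len(nGroups))
            out[k, ] <- rowMeans(rpm[, grp == k, drop = FALSE])
        out
    }
    tss <- ifelse(plus, start(g), end(g))
    tes <- ifelse(plus, end(g), start(g))
    list(tss = profileAt(tss), tes = profileAt(tes),
         positions = rel, groups = setNames(grp, ids))
}
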