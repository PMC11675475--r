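#' Construct a GenomeAnnotation
#'
#' @param chromSizes Named integer/numeric vector of chromosome lengths (bp).
#' @param genes GRanges of gene extents with `gene_id` metadata and +/- strand.
#' @param exons,utr5,utr3 GRanges with `gene_id` metadata (may be empty).
#' @return A [GenomeAnnotation-class] object.
#' @export
makeGenomeAnnotation <- function(chromSizes, genes = GRanges(),
                                 exons = GRanges(), utr5 = GRanges(),
                                 utr3 = GRanges()) {
    cs <- setNames(as.integer(chromSizes), names(chromSizes))
    new("GenomeAnnotation", chromSizes = cs, genes = genes, exons = exons,
        utr5 = utr5, utr3 = utr3)
}

#' Strand-oriented TSS and TES positions
#'
#' The TSS is the 5' end of the gene in strand orientation (start on +,
#' end on -); the TES the 3' end.
#'
#' @param annotation A GenomeAnnotation.
#' @return Named integer vector of positions (1-based), names = gene ids.
#' @export
tssPositions <- function(annotation) {
    g <- geneModels(annotation)
    pos <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
    setNames(as.integer(pos), g$gene_id)
}

#' @rdname tssPositions
#' @export
tesPositions <- function(annotation) {
    g <- geneModels(annotation)
    pos <- ifelse(as.character(strand(g)) == "+", end(g), start(g))
    setNames(as.integer(pos), g$gene_id)
}

#' Promoter windows upstream of TSSs
#'
#' The promoter is the `width` bp immediately upstream of the TSS in strand
#' orientation (TSS itself excluded), clipped at chromosome edges.
#'
#' @param annotation A GenomeAnnotation.
#' @param width Window width in bp (default 2000).
#' @return GRanges with `gene_id` metadata, one window per gene (genes whose
#'   window is fully clipped away are dropped).
#' @export
promoterWindows <- function(annotation, width = 2000) {
    g <- geneModels(annotation)
    if (!length(g)) return(GRanges())
    tss <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
    plus <- as.character(strand(g)) == "+"
    s <- ifelse(plus, tss - width, tss + 1)
    e <- ifelse(plus, tss - 1, tss + width)
    lim <- chromSizes(annotation)[as.character(seqnames(g))]
    s <- pmax(s, 1L)
    e <- pmin(e, lim)
    keep <- s <= e
    gr <- GRanges(seqnames(g)[keep], IRanges(s[keep], e[keep]),
                  strand = strand(g)[keep])
    gr$gene_id <- g$gene_id[keep]
    gr
}

#' Disjoint feature-category partition of the genome
#'
#' Builds a set of disjoint unstranded intervals covering every base of the
#' genome, each labeled with one feature category under the precedence
#' promoter > utr5 > utr3 > exon > intron > intergenic.
#'
#' @param annotation A GenomeAnnotation.
#' @param promoterWidth Promoter window width in bp.
#' @return GRanges with a `category` metadata column; intervals are disjoint
#'   and cover the genome.
#' @export
categoryPartition <- function(annotation, promoterWidth = 2000) {
    cs <- chromSizes(annotation)
    genome <- GRanges(names(cs), IRanges(1L, as.integer(cs)))
    strip <- function(x) {
        x <- granges(x)
        strand(x) <- "*"
        reduce(x)
    }
    takeNext <- function(candidate, occupied) {
        if (!length(candidate)) return(GRanges())
        if (!length(occupied)) return(candidate)
        GenomicRanges::setdiff(candidate, occupied)
    }
    prom <- strip(promoterWindows(annotation, promoterWidth))
    occ <- prom
    u5 <- takeNext(strip(utrRanges(annotation, "utr5")), occ)
    occ <- reduce(c(occ, u5))
    u3 <- takeNext(strip(utrRanges(annotation, "utr3")), occ)
    occ <- reduce(c(occ, u3))
    ex <- takeNext(strip(exonRanges(annotation)), occ)
    occ <- reduce(c(occ, ex))
    intr <- takeNext(strip(geneModels(annotation)), occ)
    occ <- reduce(c(occ, intr))
    inter <- takeNext(genome, occ)
    pieces <- list(promoter = prom, utr5 = u5, utr3 = u3, exon = ex,
                   intron = intr, intergenic = inter)
    out <- do.call(c, unname(pieces))
    out$category <- rep(names(pieces), vapply(pieces, length, 1L))
    GenomicRanges::sort(out)
}

#' Classify peaks into feature categories
#'
#' Each peak is classified by the category of its summit position (metadata
#' column `summit`, absolute 1-based position) or, when no summit is present,
#' its midpoint. Classification is total: every position maps to exactly one
#' category of the precedence partition.
#'
#' @param peaks GRanges of peaks (optionally with a `summit` column).
#' @param annotation A GenomeAnnotation, or a precomputed [categoryPartition()]
#'   GRanges (pass the latter when classifying many sets against one genome).
#' @param promoterWidth Promoter window width in bp.
#' @return Factor of categories, one per peak, levels = [featureCategories()].
#' @export
classifyPeaks <- function(peaks, annotation, promoterWidth = 2000) {
    part <- if (is(annotation, "GenomeAnnotation"))
        categoryPartition(annotation, promoterWidth) else annotation
    if (!length(peaks))
        return(factor(character(0), levels = featureCategories()))
    chromOK <- as.character(seqnames(peaks)) %in%
        as.character(seqlevels(part))
    if (!all(chromOK))
        stop("peak on unknown chromosome: ",
             paste(unique(as.character(seqnames(peaks))[!chromOK]),
                   collapse = ", "))
    pos <- classificationPositions(peaks)
    pts <- GRanges(seqnames(peaks), IRanges(pos, pos))
    hit <- findOverlaps(pts, part, select = "first")
    if (anyNA(hit))
        stop("position outside the category partition (peak beyond ",
             "chromosome bounds?)")
    factor(part$category[hit], levels = featureCategories())
}

## Absolute 1-based classification position: summit when present, else midpoint.
classificationPositions <- function(peaks) {
    pos <- start(peaks) + floor((width(peaks) - 1) / 2)
    if (!is.null(peaks$summit)) {
        s <- peaks$summit
        use <- !is.na(s)
        pos[use] <- s[use]
    }
    as.integer(pos)
}

#' Category counts, proportions, and length statistics of a peak set
#'
#' @param peaks GRanges of peaks.
#' @param annotation GenomeAnnotation or precomputed partition.
#' @param promoterWidth Promoter window width in bp.
#' @return data.frame with one row per category: count, proportion, and
#'   mean/median peak length; proportions sum to 1 (all zero for an empty
#'   set, with a warning).
#' @export
featureProportions <- function(peaks, annotation, promoterWidth = 2000) {
    cats <- featureCategories()
    if (!length(peaks)) {
        warning("empty peak set")
        return(data.frame(category = cats, count = 0L, proportion = 0,
                          mean_length = NA_real_, median_length = NA_real_))
    }
    cl <- classifyPeaks(peaks, annotation, promoterWidth)
    w <- width(peaks)
    count <- as.integer(table(cl))
    data.frame(
        category = cats,
        count = count,
        proportion = count / length(peaks),
        mean_length = vapply(cats, function(k)
            if (any(cl == k)) mean(w[cl == k]) else NA_real_, 1),
        median_length = vapply(cats, function(k)
            if (any(cl == k)) median(w[cl == k]) else NA_real_, 1),
        row.names = NULL)
}
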