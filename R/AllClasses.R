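#' Developmental stages used throughout the package
#'
#' The three phenological stages (BBCH decimal code: first, third and seventh
#' leaf unfolded) that label every sample, peak set and comparison.
#'
#' @return Character vector of the three stage labels.
#' @export
acrStages <- function() c("BBCH_11", "BBCH_13", "BBCH_17")

#' Feature categories with classification precedence
#'
#' Every genomic position belongs to exactly one category; where features
#' overlap, precedence is promoter > utr5 > utr3 > exon > intron > intergenic.
#'
#' @return Character vector of the six categories, in precedence order.
#' @export
featureCategories <- function()
    c("promoter", "utr5", "utr3", "exon", "intron", "intergenic")

## ---------------------------------------------------------------------------
## GenomeAnnotation
## ---------------------------------------------------------------------------

#' GenomeAnnotation: chromosome sizes plus stranded gene models
#'
#' Holds chromosome sizes and one gene model per gene (gene extent, exons,
#' 5'/3' UTRs), all as GRanges in 1-based closed coordinates. The TSS is the
#' 5' end of the gene in strand orientation; the TES the 3' end.
#'
#' @slot chromSizes Named integer vector of chromosome lengths (bp).
#' @slot genes GRanges of gene extents with `gene_id` metadata column.
#' @slot exons GRanges of exons with `gene_id`.
#' @slot utr5 GRanges of 5' UTRs with `gene_id`.
#' @slot utr3 GRanges of 3' UTRs with `gene_id`.
#' @export
setClass("GenomeAnnotation", representation(
    chromSizes = "integer",
    genes = "GRanges",
    exons = "GRanges",
    utr5 = "GRanges",
    utr3 = "GRanges"
))

setValidity("GenomeAnnotation", function(object) {
    msgs <- character(0)
    cs <- object@chromSizes
    if (is.null(names(cs)) || anyNA(cs) || any(cs <= 0))
        msgs <- c(msgs, "chromSizes must be a named positive integer vector")
    g <- object@genes
    if (length(g)) {
        if (is.null(g$gene_id)) msgs <- c(msgs, "genes need a gene_id column")
        bad <- !(as.character(seqnames(g)) %in% names(cs))
        if (any(bad))
            msgs <- c(msgs, "gene on unknown chromosome")
        else {
            lim <- cs[as.character(seqnames(g))]
            if (any(start(g) < 1) || any(end(g) > lim))
                msgs <- c(msgs, "gene extends beyond its chromosome")
        }
        if (any(as.character(strand(g)) == "*"))
            msgs <- c(msgs, "gene strand must be + or -")
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn GenomeAnnotation Show a compact summary.
#' @param object A GenomeAnnotation.
#' @export
setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation:", length(object@chromSizes), "chromosomes (",
        sum(as.numeric(object@chromSizes)), "bp ),",
        length(object@genes), "genes\n")
})

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' SimConfig: parameters of the synthetic multi-stage ATAC/RNA dataset
#'
#' Created with [simConfig()]; see that constructor for field semantics and
#' defaults.
#'
#' @slot seed Integer master seed.
#' @slot chromosomeLengths Integer vector of chromosome lengths (bp).
#' @slot nGenes Integer number of gene models.
#' @slot nSharedPeaks Integer count of peaks present at all stages.
#' @slot nSpecificPeaks Named integer triple of stage-specific peak counts.
#' @slot categoryPlacementProbs Named numeric, placement probability per
#'   feature category (sums to 1).
#' @slot categoryLengthParams Numeric matrix (categories x 2: mean, sd bp).
#' @slot nbDispersion Positive numeric NB dispersion for counts.
#' @slot librarySizes Named numeric per-sample ATAC library sizes.
#' @slot rnaLibrarySizes Named numeric per-sample RNA library sizes.
#' @slot dpiLog2fc Positive numeric planted differential-intensity effect.
#' @slot fracDpi Proportion of shared peaks given a DPI effect.
#' @slot expressionCoupling Non-negative strength linking promoter
#'   accessibility to log2 FPKM.
#' @slot nDiscordant Integer number of planted discordant genes.
#' @slot motifConsensus Character vector of IUPAC consensus motifs.
#' @slot clusterArchetypes Numeric 8 x 3 matrix of stage-level log2 offsets.
#' @slot nClusterGenes Integer number of genes planted into archetypes.
#' @slot replicateJitter Integer maximal per-edge replicate jitter (bp).
#' @slot fragmentsPerSample Integer ATAC fragments simulated per sample.
#' @slot backgroundFragmentFrac Proportion of background (non-peak) fragments.
#' @slot silentGeneFrac Proportion of genes with zero expression.
#' @slot expressionNoiseSd Per-sample log2-FPKM noise standard deviation.
#' @slot motifTargetFrac Proportion of target promoters receiving a motif.
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    chromosomeLengths = "integer",
    nGenes = "integer",
    nSharedPeaks = "integer",
    nSpecificPeaks = "integer",
    categoryPlacementProbs = "numeric",
    categoryLengthParams = "matrix",
    nbDispersion = "numeric",
    librarySizes = "numeric",
    rnaLibrarySizes = "numeric",
    dpiLog2fc = "numeric",
    fracDpi = "numeric",
    expressionCoupling = "numeric",
    nDiscordant = "integer",
    motifConsensus = "character",
    clusterArchetypes = "matrix",
    nClusterGenes = "integer",
    replicateJitter = "integer",
    fragmentsPerSample = "integer",
    backgroundFragmentFrac = "numeric",
    silentGeneFrac = "numeric",
    expressionNoiseSd = "numeric",
    motifTargetFrac = "numeric"
))

setValidity("SimConfig", function(object) {
    msgs <- character(0)
    p <- object@categoryPlacementProbs
    if (abs(sum(p) - 1) > 1e-8)
        msgs <- c(msgs, "categoryPlacementProbs must sum to 1")
    if (!all(names(p) %in% featureCategories()))
        msgs <- c(msgs, "unknown feature category in placement probs")
    if (any(object@chromosomeLengths <= 0))
        msgs <- c(msgs, "chromosome lengths must be positive")
    if (any(object@categoryLengthParams <= 0))
        msgs <- c(msgs, "category length parameters must be positive")
    if (object@nbDispersion <= 0)
        msgs <- c(msgs, "nbDispersion must be positive")
    if (object@nDiscordant > object@nGenes)
        msgs <- c(msgs, "nDiscordant cannot exceed nGenes")
    if (length(object@nSpecificPeaks) != 3L)
        msgs <- c(msgs, "nSpecificPeaks must have one entry per stage")
    if (!identical(dim(object@clusterArchetypes), c(8L, 3L)))
        msgs <- c(msgs, "clusterArchetypes must be an 8 x 3 matrix")
    if (object@fracDpi < 0 || object@fracDpi > 1)
        msgs <- c(msgs, "fracDpi must be a proportion")
    if (object@expressionCoupling < 0)
        msgs <- c(msgs, "expressionCoupling must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn SimConfig Show a compact summary.
#' @param object A SimConfig.
#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: seed", object@seed, "|",
        length(object@chromosomeLengths), "chromosomes,",
        object@nGenes, "genes,",
        object@nSharedPeaks, "shared +",
        paste(object@nSpecificPeaks, collapse = "/"), "specific peaks\n")
})

## ---------------------------------------------------------------------------
## TruthSet
## ---------------------------------------------------------------------------

#' TruthSet: planted ground-truth labels of a synthetic dataset
#'
#' @slot peakLabels data.frame(peak_id, label in {shared, specific}, stage).
#' @slot dpiEffects data.frame(peak_id, one log2-offset column per stage).
#' @slot peakGene data.frame(peak_id, gene_id) for promoter-planted peaks.
#' @slot geneClusters data.frame(gene_id, cluster in 1..8).
#' @slot discordantGenes Character vector of discordant gene ids.
#' @slot motifPlacements data.frame(gene_id, peak_id, motif, offset).
#' @export
setClass("TruthSet", representation(
    peakLabels = "data.frame",
    dpiEffects = "data.frame",
    peakGene = "data.frame",
    geneClusters = "data.frame",
    discordantGenes = "character",
    motifPlacements = "data.frame"
))

#' @describeIn TruthSet Show a compact summary.
#' @param object A TruthSet.
#' @export
setMethod("show", "TruthSet", function(object) {
    cat("TruthSet:", nrow(object@peakLabels), "labeled peaks (",
        sum(object@peakLabels$label == "specific"), "specific ),",
        sum(rowSums(abs(object@dpiEffects[, -1, drop = FALSE])) > 0),
        "DPI peaks,", nrow(object@geneClusters), "cluster genes,",
        length(object@discordantGenes), "discordant genes\n")
})

## ---------------------------------------------------------------------------
## StageACRSet / SpecificityPartition
## ---------------------------------------------------------------------------

#' StageACRSet: consolidated replicate-supported ACRs of one stage
#'
#' @slot stage Character stage label.
#' @slot peaks GRanges of merged, pairwise-disjoint ACRs; metadata may carry
#'   summed per-sample counts.
#' @slot source Character identifiers of the contributing replicate sets.
#' @export
setClass("StageACRSet", representation(
    stage = "character",
    peaks = "GRanges",
    source = "character"
))

setValidity("StageACRSet", function(object) {
    p <- object@peaks
    if (length(p) > 1) {
        r <- reduce(p, ignore.strand = TRUE)
        if (length(r) != length(p))
            return("peaks must be disjoint after consolidation")
    }
    TRUE
})

#' @describeIn StageACRSet Show a compact summary.
#' @param object A StageACRSet.
#' @export
setMethod("show", "StageACRSet", function(object) {
    cat("StageACRSet", object@stage, ":", length(object@peaks),
        "ACRs,", sum(width(object@peaks)), "bp\n")
})

#' SpecificityPartition: stage-specific / partial / common ACR classes
#'
#' The three classes partition the merged union of all stage sets: a region
#' is specific if supported by exactly one stage, partial if by exactly two,
#' common if by all three.
#'
#' @slot common GRanges of tri-stage regions.
#' @slot specific Named list of GRanges, one per stage.
#' @slot partial GRanges of two-stage regions (metadata column `stages`).
#' @slot unionSize Integer total number of merged union regions.
#' @export
setClass("SpecificityPartition", representation(
    common = "GRanges",
    specific = "list",
    partial = "GRanges",
    unionSize = "integer"
))

setValidity("SpecificityPartition", function(object) {
    n <- length(object@common) + length(object@partial) +
        sum(vapply(object@specific, length, 1L))
    if (n != object@unionSize)
        return("classes must partition the merged union")
    TRUE
})

#' @describeIn SpecificityPartition Show a compact summary.
#' @param object A SpecificityPartition.
#' @export
setMethod("show", "SpecificityPartition", function(object) {
    cat("SpecificityPartition:", length(object@common), "common,",
        paste(vapply(object@specific, length, 1L), collapse = "/"),
        "specific,", length(object@partial), "partial\n")
})
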