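#' Accessors for package classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x An object of the documented class.
#' @param ... Further arguments (unused).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromSizes", function(x, ...) standardGeneric("chromSizes"))

#' @rdname accessors
#' @export
setGeneric("geneModels", function(x, ...) standardGeneric("geneModels"))

#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x, ...) standardGeneric("exonRanges"))

#' @rdname accessors
#' @export
setGeneric("utrRanges", function(x, which = c("utr5", "utr3"), ...)
    standardGeneric("utrRanges"))

#' @rdname accessors
#' @export
setGeneric("acrPeaks", function(x, ...) standardGeneric("acrPeaks"))

#' @rdname accessors
#' @export
setGeneric("acrStage", function(x, ...) standardGeneric("acrStage"))

#' @rdname accessors
#' @export
setMethod("chromSizes", "GenomeAnnotation", function(x, ...) x@chromSizes)

#' @rdname accessors
#' @export
setMethod("geneModels", "GenomeAnnotation", function(x, ...) x@genes)

#' @rdname accessors
#' @export
setMethod("exonRanges", "GenomeAnnotation", function(x, ...) x@exons)

#' @rdname accessors
#' @export
setMethod("utrRanges", "GenomeAnnotation",
    function(x, which = c("utr5", "utr3"), ...) {
        which <- match.arg(which)
        if (which == "utr5") x@utr5 else x@utr3
    })

#' @rdname accessors
#' @export
setMethod("acrPeaks", "StageACRSet", function(x, ...) x@peaks)

#' @rdname accessors
#' @export
setMethod("acrStage", "StageACRSet", function(x, ...) x@stage)

#' TruthSet accessors
#'
#' @param x A TruthSet.
#' @param ... Unused.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
setGeneric("peakLabels", function(x, ...) standardGeneric("peakLabels"))

#' @rdname truth-accessors
#' @export
setGeneric("dpiEffects", function(x, ...) standardGeneric("dpiEffects"))

#' @rdname truth-accessors
#' @export
setGeneric("peakGeneTruth", function(x, ...) standardGeneric("peakGeneTruth"))

#' @rdname truth-accessors
#' @export
setGeneric("geneClusters", function(x, ...) standardGeneric("geneClusters"))

#' @rdname truth-accessors
#' @export
setGeneric("discordantGenes", function(x, ...)
    standardGeneric("discordantGenes"))

#' @rdname truth-accessors
#' @export
setGeneric("motifPlacements", function(x, ...)
    standardGeneric("motifPlacements"))

#' @rdname truth-accessors
#' @export
setMethod("peakLabels", "TruthSet", function(x, ...) x@peakLabels)

#' @rdname truth-accessors
#' @export
setMethod("dpiEffects", "TruthSet", function(x, ...) x@dpiEffects)

#' @rdname truth-accessors
#' @export
setMethod("peakGeneTruth", "TruthSet", function(x, ...) x@peakGene)

#' @rdname truth-accessors
#' @export
setMethod("geneClusters", "TruthSet", function(x, ...) x@geneClusters)

#' @rdname truth-accessors
#' @export
setMethod("discordantGenes", "TruthSet", function(x, ...) x@discordantGenes)

#' @rdname truth-accessors
#' @export
setMethod("motifPlacements", "TruthSet", function(x, ...) x@motifPlacements)

#' @rdname accessors
#' @export
setGeneric("specificACRs", function(x, ...) standardGeneric("specificACRs"))

#' @rdname accessors
#' @export
setGeneric("commonACRs", function(x, ...) standardGeneric("commonACRs"))

#' @rdname accessors
#' @export
setGeneric("partialACRs", function(x, ...) standardGeneric("partialACRs"))

#' @rdname accessors
#' @export
setMethod("specificACRs", "SpecificityPartition", function(x, ...) x@specific)

#' @rdname accessors
#' @export
setMethod("commonACRs", "SpecificityPartition", function(x, ...) x@common)

#' @rdname accessors
#' @export
setMethod("partialACRs", "SpecificityPartition", function(x, ...) x@partial)
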