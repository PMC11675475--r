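#' Consolidate two replicate peak sets into one stage ACR set
#'
#' Peaks overlapping (>= 1 bp) a peak of the other replicate are retained;
#' retained peaks are merged into union intervals. When a peak-by-sample
#' count matrix is supplied (rows named by peak id), counts of the
#' constituent peaks are summed per merged ACR.
#'
#' @param rep1,rep2 GRanges of replicate peak calls (metadata `peak_id`).
#' @param stage Stage label for the resulting set.
#' @param counts Optional numeric matrix (peak id x sample).
#' @param source Identifiers of the replicate inputs.
#' @return A [StageACRSet-class]; empty (with a warning) when either
#'   replicate is empty or no peak is reciprocally supported.
#' @export
consolidateReplicates <- function(rep1, rep2, stage = "stage",
                                  counts = NULL,
                                  source = c("rep1", "rep2")) {
    if (!length(rep1) || !length(rep2)) {
        warning("empty replicate peak set; returning empty stage set")
        return(new("StageACRSet", stage = stage, peaks = GRanges(),
                   source = source))
    }
    hits <- findOverlaps(rep1, rep2, ignore.strand = TRUE)
    k1 <- unique(queryHits(hits))
    k2 <- unique(subjectHits(hits))
    if (!length(k1)) {
        warning("no reciprocally supported peaks")
        return(new("StageACRSet", stage = stage, peaks = GRanges(),
                   source = source))
    }
    supported <- c(granges(rep1[k1]), granges(rep2[k2]))
    supported$peak_id <- c(peakIds(rep1)[k1], peakIds(rep2)[k2])
    merged <- reduce(granges(supported), ignore.strand = TRUE)
    merged$peak_id <- paste0("ACR_", stage, "_",
                             formatC(seq_along(merged), width = 5, flag = "0"))
    if (!is.null(counts)) {
        ov <- findOverlaps(merged, supported, ignore.strand = TRUE)
        agg <- matrix(0, nrow = length(merged), ncol = ncol(counts),
                      dimnames = list(merged$peak_id, colnames(counts)))
        constituents <- split(supported$peak_id[subjectHits(ov)],
                              queryHits(ov))
        for (i in names(constituents)) {
            ids <- unique(constituents[[i]])
            ids <- ids[ids %in% rownames(counts)]
            if (length(ids))
                agg[as.integer(i), ] <-
                    colSums(counts[ids, , drop = FALSE])
        }
        mcols(merged)$counts <- agg
    }
    new("StageACRSet", stage = stage, peaks = merged, source = source)
}

peakIds <- function(gr) {
    if (!is.null(gr$peak_id)) gr$peak_id else paste0("peak_", seq_along(gr))
}

#' Partition the merged ACR union into specific, partial and common classes
#'
#' All stage sets are merged into a union of disjoint regions; each region
#' is classified by how many stages support it (>= 1 bp overlap with that
#' stage's consolidated peaks): one stage = stage-specific, two = partial,
#' all three = common.
#'
#' @param stageSets Named list of three [StageACRSet-class] objects.
#' @return A [SpecificityPartition-class].
#' @export
classifySpecificity <- function(stageSets) {
    stopifnot(length(stageSets) == 3)
    stages <- vapply(stageSets, acrStage, "")
    names(stageSets) <- stages
    allPeaks <- do.call(c, unname(lapply(stageSets, function(s)
        granges(acrPeaks(s)))))
    if (!length(allPeaks))
        return(new("SpecificityPartition", common = GRanges(),
                   specific = setNames(
                       rep(list(GRanges()), 3), stages),
                   partial = GRanges(), unionSize = 0L))
    u <- reduce(allPeaks, ignore.strand = TRUE)
    pres <- vapply(stageSets, function(s)
        countOverlaps(u, acrPeaks(s), ignore.strand = TRUE) > 0,
        logical(length(u)))
    pres <- matrix(pres, nrow = length(u),
                   dimnames = list(NULL, stages))
    nPresent <- rowSums(pres)
    specific <- lapply(stages, function(s)
        u[nPresent == 1 & pres[, s]])
    names(specific) <- stages
    partial <- u[nPresent == 2]
    if (length(partial))
        partial$stages <- apply(pres[nPresent == 2, , drop = FALSE], 1,
                                function(z) paste(stages[z], collapse = ","))
    common <- u[nPresent == 3]
    if (length(common))
        common$peak_id <- paste0("ACR_common_",
                                 formatC(seq_along(common), width = 5,
                                         flag = "0"))
    new("SpecificityPartition", common = common, specific = specific,
        partial = partial, unionSize = length(u))
}

#' Sum per-sample counts of base peaks over target regions
#'
#' Maps each region to the base peaks it overlaps and sums their counts,
#' giving a count matrix on the regions (e.g. tri-stage common ACRs).
#'
#' @param regions GRanges of target regions (metadata `peak_id` used as
#'   rownames when present).
#' @param basePeaks GRanges of counted peaks with `peak_id`.
#' @param counts Numeric matrix (base peak id x sample).
#' @return Numeric matrix (region x sample).
#' @export
countsForRegions <- function(regions, basePeaks, counts) {
    out <- matrix(0, nrow = length(regions), ncol = ncol(counts),
                  dimnames = list(
                      if (!is.null(regions$peak_id)) regions$peak_id else
                          paste0("region_", seq_along(regions)),
                      colnames(counts)))
    ov <- findOverlaps(regions, basePeaks, ignore.strand = TRUE)
    ids <- split(peakIds(basePeaks)[subjectHits(ov)], queryHits(ov))
    for (i in names(ids)) {
        rows <- unique(ids[[i]])
        rows <- rows[rows %in% rownames(counts)]
        if (length(rows))
            out[as.integer(i), ] <- colSums(counts[rows, , drop = FALSE])
    }
    out
}

#' Permutation-null fold enrichment of ACRs over feature categories
#'
#' Draws `nPermutations` random region sets matched to the observed set
#' (same number of regions; same lengths when `lengthMatched`, or a fixed
#' width otherwise), placing each region on a chromosome chosen with
#' probability proportional to chromosome length and a start uniform such
#' that the region fits. Each random set is classified by feature category;
#' the per-category mean over permutations is the random control, fold =
#' observed / expected mean, and one-sided empirical p-values use the +1
#' correction so p is never 0.
#'
#' @param acrs GRanges of observed ACRs.
#' @param annotation A GenomeAnnotation.
#' @param nPermutations Number of random sets (default 5000).
#' @param seed Optional integer seed.
#' @param lengthMatched Match the observed length multiset (default TRUE).
#' @param fixedWidth Region width when `lengthMatched = FALSE`.
#' @param promoterWidth Promoter window width for classification.
#' @param sampler Optional function(lengths, chromSizes) returning a GRanges
#'   of one random region set; overrides the built-in placement (testing
#'   hook).
#' @return data.frame per category: observed, expected_mean, expected_sd
#'   (the Monte-Carlo spread of a single random draw's count), fold,
#'   p_enrich, p_deplete, n_permutations.
#' @export
permutationEnrichment <- function(acrs, annotation, nPermutations = 5000,
                                  seed = NULL, lengthMatched = TRUE,
                                  fixedWidth = NULL, promoterWidth = 2000,
                                  sampler = NULL) {
    stopifnot(nPermutations >= 1)
    if (!is.null(seed)) set.seed(seed)
    part <- categoryPartition(annotation, promoterWidth)
    cats <- featureCategories()
    obs <- table(classifyPeaks(acrs, part))[cats]
    lens <- if (lengthMatched) width(acrs) else
        rep(as.integer(fixedWidth), length(acrs))
    cs <- chromSizes(annotation)
    if (max(lens) > max(cs))
        stop("region longer than every chromosome")
    n <- length(lens)
    counts <- matrix(0L, nrow = 6, ncol = nPermutations,
                     dimnames = list(cats, NULL))
    if (!is.null(sampler)) {
        for (j in seq_len(nPermutations)) {
            rnd <- sampler(lens, cs)
            counts[, j] <- as.integer(table(classifyPeaks(rnd, part))[cats])
        }
    } else {
        ntot <- n * nPermutations
        lenAll <- rep(lens, nPermutations)
        if (max(lens) <= min(cs)) {
            ci <- sample.int(length(cs), ntot, replace = TRUE,
                             prob = cs / sum(cs))
        } else {
            ci <- integer(ntot)
            for (L in unique(lenAll)) {
                idx <- which(lenAll == L)
                feas <- which(cs >= L)
                ci[idx] <- feas[sample.int(length(feas), length(idx),
                                           replace = TRUE,
                                           prob = cs[feas] / sum(cs[feas]))]
            }
        }
        startAll <- 1L + as.integer(floor(runif(ntot) *
                                          (cs[ci] - lenAll + 1)))
        mid <- startAll + (lenAll - 1L) %/% 2L
        pts <- GRanges(names(cs)[ci], IRanges(mid, mid))
        hit <- findOverlaps(pts, part, select = "first")
        catIdx <- match(part$category[hit], cats)
        permIdx <- rep(seq_len(nPermutations), each = n)
        counts[] <- tabulate(catIdx + 6L * (permIdx - 1L),
                             nbins = 6L * nPermutations)
    }
    expected <- rowMeans(counts)
    expectedSd <- apply(counts, 1, sd)
    obsv <- as.integer(obs)
    obsv[is.na(obsv)] <- 0L
    data.frame(
        category = cats,
        observed = obsv,
        expected_mean = expected,
        expected_sd = expectedSd,
        fold = ifelse(expected > 0, obsv / expected, NA_real_),
        p_enrich = (1 + rowSums(counts >= obsv)) / (nPermutations + 1),
        p_deplete = (1 + rowSums(counts <= obsv)) / (nPermutations + 1),
        n_permutations = nPermutations,
        row.names = NULL)
}

#' Chromosome-level ACR density versus normalized chromosome length
#'
#' Normalized chromatin length for chromosome c is
#' total peak count x length(c) / total genome length; the Pearson
#' correlation between normalized lengths and per-chromosome peak counts
#' summarizes whether longer chromosomes carry proportionally more ACRs.
#'
#' @param acrs GRanges of ACRs.
#' @param chromSizes Named vector of chromosome lengths.
#' @return list(table = per-chromosome data.frame, r, r2).
#' @export
chromosomeCorrelation <- function(acrs, chromSizes) {
    if (length(chromSizes) < 2)
        stop("correlation undefined with fewer than 2 chromosomes")
    counts <- vapply(names(chromSizes), function(ch)
        sum(as.character(seqnames(acrs)) == ch), 1L)
    total <- length(acrs)
    normLen <- total * as.numeric(chromSizes) / sum(as.numeric(chromSizes))
    r <- cor(normLen, counts)
    list(table = data.frame(chrom = names(chromSizes),
                            length = as.numeric(chromSizes),
                            normalized_length = normLen,
                            count = counts, row.names = NULL),
         r = r, r2 = r^2)
}
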