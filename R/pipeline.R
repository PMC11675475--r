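#' Run the full integrative analysis on a simulated (or assembled) dataset
#'
#' Consolidates replicates per stage, partitions the ACR union into
#' specific/partial/common classes, quantifies common-ACR counts, runs the
#' differential peak-intensity (DPI) test per stage pair, filters expressed
#' genes and calls DEGs, assigns promoter ACRs, clusters the DEG union into
#' archetypes, integrates DPI with DEG direction, and computes the
#' per-gene intensity-expression correlation summary and the
#' chromosome-density correlation.
#'
#' @param sim A dataset list as returned by [simulateDataset()].
#' @param clusterSeed Seed for the k-means starts (default: the dataset
#'   seed + 7).
#' @return A list with elements stageSets, partition, commonCounts,
#'   dpi (per-comparison results), expressed, deg, assignment, clusters,
#'   integration, correlation, chromCorr.
#' @export
analyzeSimulation <- function(sim, clusterSeed = NULL) {
    config <- sim$config
    if (is.null(clusterSeed)) clusterSeed <- config@seed * 1000 + 7
    stages <- acrStages()
    samples <- sampleNames()
    stageOf <- sampleStages(samples)
    stageSets <- lapply(stages, function(st)
        consolidateReplicates(sim$stageRepPeaks[[st]][["R1"]],
                              sim$stageRepPeaks[[st]][["R2"]],
                              stage = st,
                              source = paste0(st, "_R", 1:2)))
    names(stageSets) <- stages
    partition <- classifySpecificity(stageSets)
    common <- commonACRs(partition)
    commonCounts <- countsForRegions(common, sim$basePeaks, sim$atacCounts)
    sf <- medianRatioSizeFactors(commonCounts)
    dpi <- list()
    for (pr in utils::combn(stages, 2, simplify = FALSE)) {
        lab <- paste(pr[1], "vs", pr[2])
        dpi[[lab]] <- nbTest(commonCounts,
                             groupA = which(stageOf == pr[1]),
                             groupB = which(stageOf == pr[2]))
    }
    fpkm <- sim$expression$fpkm
    expressed <- filterExpressed(fpkm, stageOf)
    deg <- identifyDEGs(sim$expression$counts, stageOf, genes = expressed)
    assignment <- assignPromoterACRs(common, sim$annotation)
    clusters <- if (length(deg$union) >= 8)
        clusterDEGs(fpkm, stageOf, deg$union, k = 8, seed = clusterSeed,
                    archetypes = config@clusterArchetypes) else NULL
    integration <- integrateDPIDEG(dpi, assignment, deg$results)
    ## stage-level normalized intensities and mean FPKM
    norm <- sweep(commonCounts, 2, sf, "/")
    peakIntensity <- vapply(stages, function(st)
        rowMeans(norm[, stageOf == st, drop = FALSE]),
        numeric(nrow(norm)))
    rownames(peakIntensity) <- rownames(commonCounts)
    stageFpkm <- vapply(stages, function(st)
        rowMeans(fpkm[, stageOf == st, drop = FALSE]),
        numeric(nrow(fpkm)))
    rownames(stageFpkm) <- rownames(fpkm)
    ## correlate the dynamics that the DPI test flagged: intensity of the
    ## significant promoter DPI peaks vs their gene's expression
    sigPeaks <- unique(unlist(lapply(dpi, function(r)
        r$feature[r$significant])))
    sigAssignment <- assignment[assignment$peak_id %in% sigPeaks, ,
                                drop = FALSE]
    correlation <- intensityExpressionCorrelation(
        peakIntensity, stageFpkm, sigAssignment)
    chromCorr <- chromosomeCorrelation(
        acrPeaks(stageSets[[1]]), chromSizes(sim$annotation))
    list(stageSets = stageSets, partition = partition,
         commonCounts = commonCounts, dpi = dpi, expressed = expressed,
         deg = deg, assignment = assignment, clusters = clusters,
         integration = integration, correlation = correlation,
         chromCorr = chromCorr, peakIntensity = peakIntensity,
         stageFpkm = stageFpkm)
}

#' Recovery metrics of an analysis against the planted truth
#'
#' @param sim A dataset list from [simulateDataset()].
#' @param analysis The result of [analyzeSimulation()].
#' @return Named list of metrics: stage-specificity recall,
#'   promoter-assignment recall, DPI recall and sign agreement, cluster
#'   adjusted Rand index, discordant-gene recovery, intensity-expression
#'   fraction positive and median r, and the chromosome-density r^2.
#' @export
recoverySummary <- function(sim, analysis) {
    truth <- sim$truth
    base <- sim$basePeaks
    lab <- peakLabels(truth)
    ## stage-specificity recall: planted specific peaks recovered in the
    ## right class
    specIdx <- which(lab$label == "specific")
    okSpec <- vapply(acrStages(), function(st) {
        idx <- specIdx[lab$stage[specIdx] == st]
        reg <- specificACRs(analysis$partition)[[st]]
        sum(countOverlaps(base[idx], reg, ignore.strand = TRUE) > 0)
    }, 1)
    specRecall <- sum(okSpec) / length(specIdx)
    ## promoter-assignment recall on shared promoter peaks
    pg <- peakGeneTruth(truth)
    sharedProm <- pg[pg$peak_id %in% lab$peak_id[lab$label == "shared"], ,
                     drop = FALSE]
    common <- commonACRs(analysis$partition)
    baseToCommon <- rep(NA_character_, length(base))
    ovAll <- findOverlaps(base, common, ignore.strand = TRUE, select = "first")
    baseToCommon[!is.na(ovAll)] <- common$peak_id[ovAll[!is.na(ovAll)]]
    names(baseToCommon) <- base$peak_id
    assignRecall <- if (nrow(sharedProm)) {
        cid <- baseToCommon[sharedProm$peak_id]
        key <- paste(analysis$assignment$peak_id, analysis$assignment$gene_id)
        mean(!is.na(cid) & paste(cid, sharedProm$gene_id) %in% key)
    } else NA_real_
    ## DPI recall and sign agreement on planted effects
    eff <- dpiEffects(truth)
    stages <- acrStages()
    hits <- 0L; found <- 0L; signOK <- 0L
    for (pr in utils::combn(stages, 2, simplify = FALSE)) {
        lfcTrue <- eff[[pr[2]]] - eff[[pr[1]]]
        idx <- which(abs(lfcTrue) > 0 & lab$label == "shared")
        if (!length(idx)) next
        res <- analysis$dpi[[paste(pr[1], "vs", pr[2])]]
        cid <- baseToCommon[eff$peak_id[idx]]
        row <- match(cid, res$feature)
        sig <- !is.na(row) & res$significant[row]
        hits <- hits + length(idx)
        found <- found + sum(sig)
        signOK <- signOK + sum(sig & sign(res$log2fc[row]) ==
                                   sign(lfcTrue[idx]))
    }
    dpiRecall <- if (hits > 0) found / hits else NA_real_
    dpiSign <- if (found > 0) signOK / found else NA_real_
    ## cluster ARI over planted cluster genes in the DEG union
    gc <- geneClusters(truth)
    ari <- NA_real_
    if (!is.null(analysis$clusters) && nrow(gc)) {
        both <- intersect(gc$gene_id, names(analysis$clusters$assignment))
        if (length(both) >= 10)
            ari <- mclust::adjustedRandIndex(
                gc$cluster[match(both, gc$gene_id)],
                analysis$clusters$assignment[both])
    }
    ## discordant recovery: planted discordant genes in off-diagonal
    ## quadrants of any comparison
    disc <- discordantGenes(truth)
    offDiag <- unique(unlist(lapply(analysis$integration, function(x)
        c(x$genes$atac_up_rna_down, x$genes$atac_down_rna_up))))
    discRecovery <- if (length(disc))
        mean(disc %in% offDiag) else NA_real_
    list(stage_specificity_recall = specRecall,
         promoter_assignment_recall = assignRecall,
         dpi_recall = dpiRecall,
         dpi_sign_agreement = dpiSign,
         cluster_ari = ari,
         discordant_recovery = discRecovery,
         fraction_positive = analysis$correlation$fraction_positive,
         median_r = analysis$correlation$median_r,
         chrom_density_r2 = analysis$chromCorr$r2)
}
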