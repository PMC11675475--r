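smallConfig <- function(seed = 5, ...) {
    simConfig(seed = seed, nGenes = 60,
              chromosomeLengths = c(chrA = 250000L, chrB = 150000L),
              nSharedPeaks = 100, nSpecificPeaks = c(30, 10, 10),
              nClusterGenes = 24, nDiscordant = 2,
              fragmentsPerSample = 20000, ...)
}

test_that("a fixed seed reproduces every artifact byte for byte", {
    d1 <- file.path(tempdir(), "sim_run1")
    d2 <- file.path(tempdir(), "sim_run2")
    unlink(c(d1, d2), recursive = TRUE)
    simulateDataset(smallConfig(), outdir = d1)
    simulateDataset(smallConfig(), outdir = d2)
    f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
    expect_equal(f1, f2)
    for (f in f1)
        expect_equal(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("an annotation without genes contains chromosomes only", {
    cfg <- simConfig(seed = 1, nGenes = 0, nSharedPeaks = 0,
                     nSpecificPeaks = c(0, 0, 0), nClusterGenes = 0,
                     nDiscordant = 0)
    ann <- simulateGenome(cfg)
    expect_equal(length(geneModels(ann)), 0L)
    expect_equal(length(chromSizes(ann)), 2L)
    gff <- tempfile(); sizes <- tempfile()
    writeAnnotationGFF3(ann, gff)
    writeChromSizes(chromSizes(ann), sizes)
    expect_equal(length(geneModels(readAnnotation(gff, sizes))), 0L)
})

test_that("gene models are stranded, within bounds, non-overlapping", {
    ann <- simulateGenome(smallConfig())
    g <- geneModels(ann)
    expect_equal(length(g), 60L)
    expect_true(all(as.character(strand(g)) %in% c("+", "-")))
    expect_true(all(countOverlaps(g, g) == 1))      # pairwise disjoint
    lim <- chromSizes(ann)[as.character(seqnames(g))]
    expect_true(all(start(g) > 2000 & end(g) <= lim))
    ## every gene has exons covering it end to end and both UTRs
    expect_true(all(g$gene_id %in% exonRanges(ann)$gene_id))
    expect_true(all(g$gene_id %in% utrRanges(ann, "utr5")$gene_id))
})

test_that("replicate peak files carry the planted per-stage peak counts", {
    cfg <- smallConfig()
    sim <- simulateDataset(cfg, sequences = FALSE)
    ## stage 1: 100 shared + 30 specific = 130 peaks in each replicate
    expect_equal(length(sim$stageRepPeaks$BBCH_11$R1), 130L)
    expect_equal(length(sim$stageRepPeaks$BBCH_11$R2), 130L)
    expect_equal(length(sim$stageRepPeaks$BBCH_13$R1), 110L)
    expect_equal(length(sim$stageRepPeaks$BBCH_17$R1), 110L)
    ## replicate jitter stays within the configured bound
    base <- sim$basePeaks
    r1 <- sim$stageRepPeaks$BBCH_11$R1
    m <- match(r1$peak_id, base$peak_id)
    expect_true(all(abs(start(r1) - start(base)[m]) <= 20))
})

test_that("promoter-only placement puts every midpoint in a window", {
    cfg <- simConfig(seed = 2, nGenes = 60,
                     chromosomeLengths = c(chrA = 250000L, chrB = 150000L),
                     categoryPlacementProbs = c(promoter = 1, utr5 = 0,
                                                exon = 0, intron = 0,
                                                utr3 = 0, intergenic = 0),
                     nSharedPeaks = 50, nSpecificPeaks = c(5, 5, 5),
                     nClusterGenes = 24, nDiscordant = 2,
                     fragmentsPerSample = 1000)
    acr <- simulateACRs(simulateGenome(cfg), cfg)
    cats <- classifyPeaks(acr$basePeaks, simulateGenome(cfg))
    expect_true(all(cats == "promoter"))
})

test_that("requesting a category absent from the annotation errors", {
    cfg <- simConfig(seed = 1, nGenes = 0,
                     categoryPlacementProbs = c(promoter = 0.5,
                                                intergenic = 0.5),
                     nSharedPeaks = 10, nSpecificPeaks = c(0, 0, 0),
                     nClusterGenes = 0, nDiscordant = 0)
    expect_error(simulateACRs(simulateGenome(cfg), cfg), "config error")
})

test_that("peak counts scale with chromosome length", {
    cfg <- simConfig(seed = 6, nGenes = 90,
                     chromosomeLengths = c(a = 200000L, b = 400000L),
                     nSharedPeaks = 300, nSpecificPeaks = c(0, 0, 0),
                     nClusterGenes = 0, nDiscordant = 0,
                     fragmentsPerSample = 1000)
    acr <- simulateACRs(simulateGenome(cfg), cfg)
    counts <- table(as.character(seqnames(acr$basePeaks)))
    ## binomial tolerance around the 1:2 planted ratio
    phat <- counts[["a"]] / sum(counts)
    se <- sqrt(1 / 3 * 2 / 3 / sum(counts))
    expect_lt(abs(phat - 1 / 3), 4 * se)
})

test_that("planted category proportions and length ordering re-emerge", {
    cfg <- simConfig(seed = 9, nGenes = 90,
                     chromosomeLengths = c(chrA = 450000L, chrB = 300000L),
                     categoryPlacementProbs = c(promoter = 0, utr5 = 0,
                                                exon = 0, intron = 0.5,
                                                utr3 = 0, intergenic = 0.5),
                     nSharedPeaks = 120, nSpecificPeaks = c(0, 0, 0),
                     nClusterGenes = 0, nDiscordant = 0,
                     fragmentsPerSample = 1000)
    ann <- simulateGenome(cfg)
    acr <- simulateACRs(ann, cfg)
    fp <- featureProportions(acr$basePeaks, ann)
    pIntron <- fp$proportion[fp$category == "intron"]
    se <- sqrt(0.25 / 120)
    expect_lt(abs(pIntron - 0.5), 4 * se)
    ## default length parameters: 3' UTR peaks longest, intergenic shortest
    sim <- defaultSim()
    fpd <- featureProportions(sim$basePeaks, sim$annotation)
    lens <- setNames(fpd$mean_length, fpd$category)
    expect_true(all(lens["utr3"] > lens[setdiff(names(lens), "utr3")]))
    expect_true(all(lens["intergenic"] <
                        lens[setdiff(names(lens), "intergenic")]))
})

test_that("planted DPI structure shows up in the count matrix", {
    sim <- defaultSim()
    eff <- dpiEffects(sim$truth)
    cnt <- sim$atacCounts
    sf <- sim$config@librarySizes / mean(sim$config@librarySizes)
    norm <- sweep(cnt, 2, sf, "/")
    st <- sampleStages()
    stageMean <- vapply(acrStages(), function(s)
        rowMeans(norm[, st == s, drop = FALSE]), numeric(nrow(norm)))
    hasEff <- rowSums(abs(eff[, acrStages()])) > 0
    ## planted 2^2-fold contrasts dominate sampling noise
    hi <- apply(eff[hasEff, acrStages()], 1, which.max)
    ratios <- vapply(which(hasEff), function(i) {
        e <- unlist(eff[i, acrStages()])
        j <- which.max(abs(e))
        stageMean[i, j] / mean(stageMean[i, -j])
    }, 1)
    planted <- vapply(which(hasEff), function(i) {
        e <- unlist(eff[i, acrStages()])
        2^e[which.max(abs(e))]
    }, 1)
    expect_gt(cor(log2(ratios), log2(planted)), 0.9)
})

test_that("expression coupling orders promoter-ACR count groups", {
    sim <- defaultSim()
    an <- defaultAnalysis()
    fpkm <- rowMeans(sim$expression$fpkm)
    gc <- expressionByACRCount(an$assignment, fpkm)
    expect_gt(gc$medians[["1"]], gc$medians[["0"]])
    expect_gt(gc$medians[["2"]], gc$medians[["1"]])
})

test_that("without coupling the ACR-expression association vanishes", {
    cfg <- smallConfig(seed = 31, expressionCoupling = 0)
    sim <- simulateDataset(cfg, sequences = FALSE)
    asg <- assignPromoterACRs(sim$basePeaks, sim$annotation)
    fpkm <- rowMeans(sim$expression$fpkm)
    nACR <- setNames(rep(0L, length(fpkm)), names(fpkm))
    tab <- table(asg$gene_id)
    nACR[names(tab)] <- as.integer(tab)
    expect_lt(abs(cor(nACR, log2(fpkm + 1))), 0.2)
})

test_that("a planted discordant gene opposes its promoter peak by design", {
    sim <- defaultSim()
    disc <- discordantGenes(sim$truth)
    expect_gt(length(disc), 0)
    eff <- dpiEffects(sim$truth)
    pg <- peakGeneTruth(sim$truth)
    st <- sampleStages()
    fpkm <- sim$expression$fpkm
    for (g in disc) {
        pk <- pg$peak_id[pg$gene_id == g]
        e <- unlist(eff[match(pk, eff$peak_id), acrStages()])
        j <- which.max(abs(e))
        expr <- vapply(acrStages(), function(s)
            mean(log2(fpkm[g, st == s] + 1)), 1)
        ## intensity moves by e[j] at stage j; expression moves opposite
        expect_lt(sign(e[j]) * (expr[j] - mean(expr[-j])), 0)
    }
})

test_that("planted motifs sit inside their recorded promoter peaks", {
    sim <- defaultSim()
    mp <- motifPlacements(sim$truth)
    expect_gt(nrow(mp), 10)
    base <- sim$basePeaks
    for (i in seq_len(min(20, nrow(mp)))) {
        pk <- base[match(mp$peak_id[i], base$peak_id)]
        s <- start(pk) + mp$offset[i]
        found <- as.character(Biostrings::subseq(
            sim$genome[[as.character(seqnames(pk))]],
            s, s + nchar(mp$motif[i]) - 1))
        expect_equal(found, mp$motif[i])
    }
})

test_that("motif enrichment separates target from background promoters", {
    sim <- defaultSim()
    mp <- motifPlacements(sim$truth)
    motif <- sim$config@motifConsensus[1]
    targetPeaks <- unique(mp$peak_id[mp$motif == motif])
    base <- sim$basePeaks
    prom <- base[!is.na(base$gene_id)]
    target <- prom[prom$peak_id %in% targetPeaks]
    bg <- prom[!(prom$peak_id %in% mp$peak_id)]
    res <- motifEnrichment(extractRegionSequences(sim$genome, target),
                           extractRegionSequences(sim$genome, bg),
                           motif)
    expect_lt(res$p, 0.01)
})

test_that("fragment files conserve counts and pile up at peaks", {
    sim <- defaultSim()
    fr <- sim$fragments[[1]]
    expect_equal(length(fr), sim$config@fragmentsPerSample)
    cs <- chromSizes(sim$annotation)
    ## fragments under peaks far exceed the genome-fraction baseline
    inPeak <- mean(countOverlaps(fr, sim$basePeaks) > 0)
    peakFrac <- genomeFraction(sim$basePeaks, cs)
    expect_gt(inPeak, 2 * peakFrac)
})

test_that("background-only fragments give a flat TSS metaprofile", {
    cfg <- smallConfig(seed = 41, backgroundFragmentFrac = 1)
    sim <- simulateDataset(cfg, sequences = FALSE)
    fpkm <- rowMeans(sim$expression$fpkm)
    mp <- metaProfile(sim$fragments[[1]], sim$annotation, fpkm,
                      binWidth = 400, nGroups = 2)
    prof <- colMeans(rbind(mp$tss[1, ], mp$tss[2, ]))
    expect_lt((max(prof) - mean(prof)) / mean(prof), 0.8)
})
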