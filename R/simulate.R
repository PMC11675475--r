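#' Default stage-pattern archetypes
#'
#' Eight stage-level log2-offset patterns whose z-scored forms are equally
#' spaced directions on the circle of centered 3-vectors, labeled to match
#' the usual developmental reading: C1/C2 peak at the first stage, C8 at the
#' second, C6/C7 at the third, C3/C5 are high except at the third stage, and
#' C4 is low only at the first stage.
#'
#' @param amplitude Pattern amplitude in log2 units (default 3).
#' @return 8 x 3 numeric matrix (rows C1..C8, columns the stages).
#' @export
defaultArchetypes <- function(amplitude = 3) {
    e1 <- c(1, -0.5, -0.5); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(0, 1, -1) / sqrt(2)
    deg <- c(C1 = 0, C2 = 300, C3 = 40, C4 = 180,
             C5 = 80, C6 = 210, C7 = 240, C8 = 120)
    ang <- deg * pi / 180
    m <- t(vapply(ang, function(a)
        amplitude * (cos(a) * e1 + sin(a) * e2), numeric(3)))
    m <- m[paste0("C", 1:8), ]
    colnames(m) <- acrStages()
    m
}

#' Construct a synthetic-dataset configuration
#'
#' Defaults define the package's standard study conditions: two chromosomes
#' (950 kb + 700 kb), 300 genes, 2 replicates x 3 stages, 450 shared peaks
#' plus (120, 40, 40) stage-specific peaks concentrated at the first stage,
#' placement probabilities dominated by promoter/intron/intergenic, 3' UTR
#' peaks longest and intergenic shortest, NB counts with dispersion 0.05,
#' 30% of shared peaks carrying a +-2 log2 intensity effect, promoter
#' accessibility coupled to expression (strength 1.5), 8 planted discordant
#' genes, and 8 expression archetypes of 25 genes each.
#'
#' @param seed Integer master seed; sub-generators use documented offsets of
#'   `seed * 1000`.
#' @param chromosomeLengths,nGenes,nSharedPeaks,nSpecificPeaks,
#'   categoryPlacementProbs,categoryLengthParams,nbDispersion,librarySizes,
#'   rnaLibrarySizes,dpiLog2fc,fracDpi,expressionCoupling,nDiscordant,
#'   motifConsensus,clusterArchetypes,nClusterGenes,replicateJitter,
#'   fragmentsPerSample,backgroundFragmentFrac,silentGeneFrac,
#'   expressionNoiseSd,motifTargetFrac See [SimConfig-class].
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1,
                      chromosomeLengths = c(chr1 = 950000L, chr2 = 700000L),
                      nGenes = 300,
                      nSharedPeaks = 450,
                      nSpecificPeaks = c(BBCH_11 = 120L, BBCH_13 = 40L,
                                         BBCH_17 = 40L),
                      categoryPlacementProbs = c(promoter = 0.30,
                                                 utr5 = 0.05, exon = 0.05,
                                                 intron = 0.30, utr3 = 0.05,
                                                 intergenic = 0.25),
                      categoryLengthParams = NULL,
                      nbDispersion = 0.05,
                      librarySizes = NULL,
                      rnaLibrarySizes = NULL,
                      dpiLog2fc = 2,
                      fracDpi = 0.3,
                      expressionCoupling = 1.5,
                      nDiscordant = 8,
                      motifConsensus = c("AGCCGCC", "ACGTGTC"),
                      clusterArchetypes = defaultArchetypes(),
                      nClusterGenes = 200,
                      replicateJitter = 20,
                      fragmentsPerSample = 150000,
                      backgroundFragmentFrac = 0.3,
                      silentGeneFrac = 0.1,
                      expressionNoiseSd = 0.4,
                      motifTargetFrac = 0.8) {
    if (is.null(categoryLengthParams)) {
        categoryLengthParams <- rbind(
            promoter = c(420, 90), utr5 = c(450, 100), exon = c(350, 80),
            intron = c(450, 100), utr3 = c(800, 150),
            intergenic = c(250, 60))
        colnames(categoryLengthParams) <- c("mean", "sd")
    }
    samples <- sampleNames()
    if (is.null(librarySizes))
        librarySizes <- setNames(
            c(1.0, 1.15, 0.9, 1.05, 1.1, 0.85) * 1e6, samples)
    if (is.null(rnaLibrarySizes))
        rnaLibrarySizes <- setNames(
            c(1.0, 1.1, 0.95, 1.05, 0.9, 1.0) * 2e7, samples)
    if (is.null(names(chromosomeLengths)))
        names(chromosomeLengths) <-
            paste0("chr", seq_along(chromosomeLengths))
    if (is.null(names(nSpecificPeaks))) names(nSpecificPeaks) <- acrStages()
    new("SimConfig", seed = as.integer(seed),
        chromosomeLengths = setNames(as.integer(chromosomeLengths),
                                     names(chromosomeLengths)),
        nGenes = as.integer(nGenes),
        nSharedPeaks = as.integer(nSharedPeaks),
        nSpecificPeaks = setNames(as.integer(nSpecificPeaks),
                                  names(nSpecificPeaks)),
        categoryPlacementProbs = categoryPlacementProbs,
        categoryLengthParams = categoryLengthParams,
        nbDispersion = nbDispersion,
        librarySizes = librarySizes,
        rnaLibrarySizes = rnaLibrarySizes,
        dpiLog2fc = dpiLog2fc, fracDpi = fracDpi,
        expressionCoupling = expressionCoupling,
        nDiscordant = as.integer(nDiscordant),
        motifConsensus = motifConsensus,
        clusterArchetypes = clusterArchetypes,
        nClusterGenes = as.integer(nClusterGenes),
        replicateJitter = as.integer(replicateJitter),
        fragmentsPerSample = as.integer(fragmentsPerSample),
        backgroundFragmentFrac = backgroundFragmentFrac,
        silentGeneFrac = silentGeneFrac,
        expressionNoiseSd = expressionNoiseSd,
        motifTargetFrac = motifTargetFrac)
}

#' Sample names of the 3-stage, 2-replicate design
#' @return Character vector of six sample names (stage_Rrep).
#' @export
sampleNames <- function() {
    as.vector(vapply(acrStages(), function(s)
        paste0(s, "_R", 1:2), character(2)))
}

#' Stage label of each sample name
#' @param samples Character sample names from [sampleNames()].
#' @return Character vector of stage labels.
#' @export
sampleStages <- function(samples = sampleNames())
    sub("_R[0-9]+$", "", samples)

## largest-remainder allocation of n items proportional to weights
allocateProportional <- function(n, weights) {
    raw <- n * weights / sum(weights)
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        o <- order(raw - base, decreasing = TRUE)
        base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
    }
    as.integer(base)
}

#' Generate a miniature annotated genome
#'
#' Genes are allocated to chromosomes proportionally to chromosome length
#' and placed left to right, each preceded by a 2 kb flank (the future
#' promoter window) and followed by an intergenic gap; strands are drawn
#' ~50/50. Every gene has 2-3 exons, a 5' UTR and a 3' UTR. Deterministic
#' for a fixed seed.
#'
#' @param config A [SimConfig-class].
#' @return A [GenomeAnnotation-class].
#' @export
simulateGenome <- function(config) {
    set.seed(config@seed * 1000 + 1)
    cs <- config@chromosomeLengths
    if (config@nGenes == 0) return(makeGenomeAnnotation(cs))
    perChrom <- allocateProportional(config@nGenes, cs)
    rows <- list(); exRows <- list(); u5Rows <- list(); u3Rows <- list()
    gid <- 0L
    for (ci in seq_along(cs)) {
        cursor <- 1L
        for (j in seq_len(perChrom[ci])) {
            gid <- gid + 1L
            geneLen <- sample(1500:2400, 1)
            gap <- sample(1000:1600, 1)
            start <- cursor + 2000L
            end <- start + geneLen - 1L
            if (end > cs[ci] - 2100L)
                stop("sizing error: genes with 2 kb flanks exceed ",
                     "chromosome ", names(cs)[ci])
            strand <- sample(c("+", "-"), 1)
            id <- sprintf("gene%04d", gid)
            rows[[gid]] <- data.frame(chrom = names(cs)[ci], start = start,
                                      end = end, strand = strand, id = id)
            ## exon/intron structure (coordinates left to right)
            nEx <- sample(2:3, 1)
            intrLens <- if (nEx > 1) sample(300:600, nEx - 1, TRUE) else
                integer(0)
            exTotal <- geneLen - sum(intrLens)
            exLens <- rep(exTotal %/% nEx, nEx)
            exLens[1] <- exLens[1] + exTotal %% nEx
            pos <- start
            for (k in seq_len(nEx)) {
                exRows[[length(exRows) + 1]] <- data.frame(
                    chrom = names(cs)[ci], start = pos,
                    end = pos + exLens[k] - 1L, strand = strand, id = id)
                pos <- pos + exLens[k] +
                    if (k < nEx) intrLens[k] else 0L
            }
            u5len <- sample(80:150, 1)
            u3len <- sample(120:250, 1)
            if (strand == "+") {
                u5 <- c(start, start + u5len - 1L)
                u3 <- c(end - u3len + 1L, end)
            } else {
                u5 <- c(end - u5len + 1L, end)
                u3 <- c(start, start + u3len - 1L)
            }
            u5Rows[[gid]] <- data.frame(chrom = names(cs)[ci],
                                        start = u5[1], end = u5[2],
                                        strand = strand, id = id)
            u3Rows[[gid]] <- data.frame(chrom = names(cs)[ci],
                                        start = u3[1], end = u3[2],
                                        strand = strand, id = id)
            cursor <- end + gap
        }
    }
    toGR <- function(lst) {
        df <- do.call(rbind, lst)
        gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                      strand = df$strand)
        gr$gene_id <- df$id
        gr
    }
    makeGenomeAnnotation(cs, genes = toGR(rows), exons = toGR(exRows),
                         utr5 = toGR(u5Rows), utr3 = toGR(u3Rows))
}

#' Generate the multi-stage ACR landscape with planted truth
#'
#' Plants `nSharedPeaks` peaks present at all stages and per-stage specific
#' peaks present at exactly one stage. Feature categories follow
#' `categoryPlacementProbs` (peak classification position guaranteed inside
#' the category), lengths follow `categoryLengthParams`, and placement is
#' width-proportional within category regions so per-chromosome counts
#' scale with chromosome length. Promoter peaks are anchored 150-1200 bp
#' upstream of a target gene's TSS; shared promoter peaks target non-cluster
#' genes, stage-specific promoter peaks preferentially target cluster genes
#' of the matching archetype (C1/C8/C7). A `fracDpi` subset of shared peaks
#' (topped up so enough promoter peaks carry an effect to host discordant
#' genes) receives a +-`dpiLog2fc` intensity effect at one designated
#' stage. Replicate peak files are jittered by at most `replicateJitter`
#' bp per edge.
#'
#' @param annotation A [GenomeAnnotation-class] from [simulateGenome()].
#' @param config A [SimConfig-class].
#' @return list(basePeaks = GRanges with peak_id/category/label/stage/
#'   gene_id, stageRepPeaks = nested list stage -> replicate -> GRanges,
#'   truth = partial truth pieces (peakLabels, dpiEffects, peakGene,
#'   geneClusters, discordantGenes)).
#' @export
simulateACRs <- function(annotation, config) {
    set.seed(config@seed * 1000 + 2)
    stages <- acrStages()
    genes <- geneModels(annotation)
    probs <- config@categoryPlacementProbs[featureCategories()]
    probs[is.na(probs)] <- 0
    part <- categoryPartition(annotation)
    regionsByCat <- split(part, part$category)
    for (cat in names(probs)[probs > 0])
        if (!(cat %in% names(regionsByCat)) ||
            !length(regionsByCat[[cat]]))
            stop("config error: category '", cat,
                 "' requested but absent from the annotation")
    nSpec <- config@nSpecificPeaks
    nTotal <- config@nSharedPeaks + sum(nSpec)
    label <- c(rep("shared", config@nSharedPeaks),
               rep("specific", sum(nSpec)))
    specStage <- c(rep(NA_character_, config@nSharedPeaks),
                   rep(names(nSpec), nSpec))
    ## pre-assign cluster genes (expression archetypes); stage-specific
    ## promoter peaks will preferentially land in their promoters
    clusterGenes <- character(0); clusterOf <- integer(0)
    if (config@nClusterGenes > 0 && length(genes)) {
        clusterGenes <- sample(genes$gene_id,
                               min(config@nClusterGenes, length(genes)))
        clusterOf <- setNames(rep(seq_len(8),
                                  length.out = length(clusterGenes)),
                              clusterGenes)
    }
    archStage <- c(BBCH_11 = 1L, BBCH_13 = 8L, BBCH_17 = 7L)
    tss <- tssPositions(annotation)
    geneChrom <- setNames(as.character(seqnames(genes)), genes$gene_id)
    geneStrand <- setNames(as.character(strand(genes)), genes$gene_id)
    ## occupancy ledger kept in plain vectors (fast incremental overlap test)
    occChrom <- character(0); occStart <- integer(0); occEnd <- integer(0)
    margin <- 2L * config@replicateJitter + 20L
    lp <- config@categoryLengthParams
    drawLen <- function(cat)
        max(100L, as.integer(round(rnorm(1, lp[cat, 1], lp[cat, 2]))))
    fits <- function(ch, s, e)
        !any(occChrom == ch & occStart <= e + margin & occEnd >= s - margin)
    csAll <- chromSizes(annotation)
    placeInPromoter <- function(gene, len) {
        ch <- geneChrom[gene]
        for (try in seq_len(30)) {
            off <- sample(150:1400, 1)
            mid <- if (geneStrand[gene] == "+") tss[gene] - off else
                tss[gene] + off
            s <- mid - len %/% 2L
            e <- s + len - 1L
            if (s >= 1 && e <= csAll[ch] && fits(ch, s, e))
                return(c(s, e))
        }
        NULL
    }
    regWidth <- lapply(regionsByCat, width)
    regChrom <- lapply(regionsByCat, function(r) as.character(seqnames(r)))
    regStart <- lapply(regionsByCat, start)
    placeInCategory <- function(cat, len) {
        w <- regWidth[[cat]]
        for (try in seq_len(60)) {
            ri <- sample.int(length(w), 1, prob = w)
            mid <- regStart[[cat]][ri] + sample.int(w[ri], 1) - 1L
            s <- mid - len %/% 2L
            ch <- regChrom[[cat]][ri]
            s <- max(1L, min(s, csAll[ch] - len + 1L))
            e <- s + len - 1L
            if (fits(ch, s, e)) return(list(ch, s, e))
        }
        stop("sizing error: could not place a '", cat,
             "' peak without overlap; genome too crowded")
    }
    cats <- sample(names(probs), nTotal, replace = TRUE, prob = probs)
    pChrom <- character(nTotal); pStart <- integer(nTotal)
    pEnd <- integer(nTotal)
    peakGene <- rep(NA_character_, nTotal)
    nonCluster <- setdiff(genes$gene_id, clusterGenes)
    for (i in seq_len(nTotal)) {
        len <- drawLen(cats[i])
        if (cats[i] == "promoter") {
            candidates <- if (label[i] == "shared") {
                nonCluster[sample.int(length(nonCluster))]
            } else {
                targetCluster <- archStage[specStage[i]]
                pool <- names(clusterOf)[clusterOf == targetCluster]
                ## fall back to non-cluster genes without a shared promoter
                ## peak, so a specific peak neither contradicts another
                ## archetype nor mixes with a shared peak's dynamics
                fallback <- setdiff(nonCluster, peakGene[!is.na(peakGene)])
                if (!length(fallback)) fallback <- nonCluster
                fallback <- fallback[sample.int(length(fallback))]
                if (length(pool) && runif(1) < config@motifTargetFrac)
                    c(pool[sample.int(length(pool))], fallback) else fallback
            }
            se <- NULL
            for (gene in candidates) {
                se <- placeInPromoter(gene, len)
                if (!is.null(se)) { peakGene[i] <- gene; break }
            }
            if (is.null(se))
                stop("sizing error: could not place a promoter peak")
            pChrom[i] <- geneChrom[gene]; pStart[i] <- se[1]
            pEnd[i] <- se[2]
        } else {
            se <- placeInCategory(cats[i], len)
            pChrom[i] <- se[[1]]; pStart[i] <- se[[2]]; pEnd[i] <- se[[3]]
        }
        occChrom <- c(occChrom, pChrom[i])
        occStart <- c(occStart, pStart[i])
        occEnd <- c(occEnd, pEnd[i])
    }
    basePeaks <- GRanges(pChrom, IRanges(pStart, pEnd))
    basePeaks$peak_id <- sprintf("peak%04d", seq_len(nTotal))
    basePeaks$category <- cats
    basePeaks$label <- label
    basePeaks$stage <- specStage
    basePeaks$gene_id <- peakGene
    ## DPI effects on shared peaks; top up promoter DPI peaks so planted
    ## discordant genes always sit under a differential promoter peak
    sharedIdx <- which(label == "shared")
    nDpi <- round(config@fracDpi * length(sharedIdx))
    dpiIdx <- if (nDpi > 0) sample(sharedIdx, nDpi) else integer(0)
    minPromDpi <- 8L * config@nDiscordant
    promShared <- sharedIdx[cats[sharedIdx] == "promoter" &
                            !is.na(peakGene[sharedIdx])]
    promDpi <- intersect(dpiIdx, promShared)
    if (length(promDpi) < minPromDpi) {
        extra <- setdiff(promShared, dpiIdx)
        nAdd <- min(length(extra), minPromDpi - length(promDpi))
        if (nAdd > 0) dpiIdx <- c(dpiIdx, sample(extra, nAdd))
    }
    eff <- matrix(0, nrow = nTotal, ncol = 3,
                  dimnames = list(basePeaks$peak_id, stages))
    if (length(dpiIdx)) {
        stageHit <- sample(1:3, length(dpiIdx), replace = TRUE)
        sgn <- sample(c(-1, 1), length(dpiIdx), replace = TRUE)
        eff[cbind(dpiIdx, stageHit)] <- sgn * config@dpiLog2fc
    }
    ## discordant genes: non-cluster genes whose single promoter peak
    ## carries a DPI effect, preferring accessibility gains (the repressor
    ## scenario: chromatin opens while expression drops) so the planted
    ## opposite-direction signal is unambiguous
    promDpiIdx <- intersect(dpiIdx, promShared)
    promCount <- table(peakGene[!is.na(peakGene)])
    singleGene <- names(promCount)[promCount == 1]
    candIdx <- promDpiIdx[peakGene[promDpiIdx] %in% singleGene]
    gain <- candIdx[rowSums(eff[candIdx, , drop = FALSE]) > 0]
    rest <- setdiff(candIdx, gain)
    ordered <- c(gain[sample.int(length(gain))],
                 rest[sample.int(length(rest))])
    discordant <- unique(peakGene[ordered])
    discordant <- discordant[seq_len(min(config@nDiscordant,
                                         length(discordant)))]
    ## emit jittered replicate files
    stageRepPeaks <- lapply(stages, function(st) {
        present <- which(label == "shared" | specStage == st)
        lapply(1:2, function(rp) {
            p <- basePeaks[present]
            j <- config@replicateJitter
            ds <- sample(seq(-j, j), length(p), replace = TRUE)
            de <- sample(seq(-j, j), length(p), replace = TRUE)
            s <- pmax(1L, start(p) + ds)
            e <- pmax(s + 50L, end(p) + de)
            cl <- chromSizes(annotation)[as.character(seqnames(p))]
            e <- pmin(e, cl)
            out <- GRanges(seqnames(p), IRanges(s, e))
            out$peak_id <- p$peak_id
            out$score <- 0
            out$summit <- pmin(pmax(classificationPositions(p), s), e)
            out[order(as.character(seqnames(out)), start(out))]
        })
    })
    names(stageRepPeaks) <- stages
    for (st in stages) names(stageRepPeaks[[st]]) <- paste0("R", 1:2)
    truth <- list(
        peakLabels = data.frame(peak_id = basePeaks$peak_id, label = label,
                                stage = specStage),
        dpiEffects = data.frame(peak_id = basePeaks$peak_id, eff,
                                check.names = FALSE,
                                row.names = NULL),
        peakGene = data.frame(peak_id = basePeaks$peak_id[!is.na(peakGene)],
                              gene_id = peakGene[!is.na(peakGene)]),
        geneClusters = data.frame(gene_id = names(clusterOf),
                                  cluster = unname(clusterOf)),
        discordantGenes = discordant)
    list(basePeaks = basePeaks, stageRepPeaks = stageRepPeaks,
         truth = truth)
}

#' Simulate per-peak Tn5 count matrices
#'
#' Counts are NB(mean = base x size factor x 2^effect, dispersion
#' `nbDispersion`); stage-specific peaks keep a 3% residual background mean
#' at absent stages.
#'
#' @param acrSim Output of [simulateACRs()].
#' @param config A [SimConfig-class].
#' @return Integer matrix (peak id x sample).
#' @export
simulateCounts <- function(acrSim, config) {
    set.seed(config@seed * 1000 + 3)
    p <- acrSim$basePeaks
    eff <- as.matrix(acrSim$truth$dpiEffects[, acrStages()])
    samples <- sampleNames()
    sf <- config@librarySizes / mean(config@librarySizes)
    baseMean <- rlnorm(length(p), log(300), 0.4)
    out <- matrix(0L, nrow = length(p), ncol = length(samples),
                  dimnames = list(p$peak_id, samples))
    stageOf <- sampleStages(samples)
    for (s in seq_along(samples)) {
        st <- stageOf[s]
        present <- p$label == "shared" | p$stage == st
        present[is.na(present)] <- TRUE
        mu <- baseMean * ifelse(present,
                                2^eff[, st],
                                0.03)
        mu <- mu * sf[s]
        out[, s] <- rnbinom(length(p), mu = mu,
                            size = 1 / config@nbDispersion)
    }
    out
}

#' Direct NB count-matrix generator for calibration and power studies
#'
#' Generates a features x samples NB count matrix for a two-group design
#' with a planted log2 effect in a fraction of features; used for null
#' (fracAffected = 0) and power simulations of the differential test.
#'
#' @param nFeatures Number of features.
#' @param nPerGroup Samples per group (default 2).
#' @param baseMean Base mean, either a scalar or per-feature vector; when
#'   NULL drawn log-normally around 300.
#' @param dispersion NB dispersion.
#' @param log2fc Planted effect size (group B over A).
#' @param fracAffected Fraction of features receiving the effect (random
#'   sign).
#' @param sizeFactors Optional per-sample factors (length 2 * nPerGroup).
#' @param seed Integer seed.
#' @return list(counts = matrix, affected = logical vector, sign = numeric
#'   vector of planted signs, groupA, groupB = column indices).
#' @export
simulateCountMatrix <- function(nFeatures, nPerGroup = 2, baseMean = NULL,
                                dispersion = 0.05, log2fc = 0,
                                fracAffected = 0, sizeFactors = NULL,
                                seed = 1) {
    set.seed(seed)
    if (is.null(baseMean)) baseMean <- rlnorm(nFeatures, log(300), 0.5)
    baseMean <- rep_len(baseMean, nFeatures)
    nS <- 2 * nPerGroup
    if (is.null(sizeFactors)) sizeFactors <- rep(1, nS)
    affected <- rep(FALSE, nFeatures)
    if (fracAffected > 0)
        affected[sample.int(nFeatures, round(fracAffected * nFeatures))] <-
            TRUE
    sgn <- ifelse(affected, sample(c(-1, 1), nFeatures, TRUE), 0)
    counts <- matrix(0L, nFeatures, nS,
                     dimnames = list(sprintf("f%05d", seq_len(nFeatures)),
                                     c(paste0("A", seq_len(nPerGroup)),
                                       paste0("B", seq_len(nPerGroup)))))
    for (s in seq_len(nS)) {
        inB <- s > nPerGroup
        mu <- baseMean * sizeFactors[s] *
            ifelse(affected & inB, 2^(sgn * log2fc), 1)
        counts[, s] <- rnbinom(nFeatures, mu = mu, size = 1 / dispersion)
    }
    list(counts = counts, affected = affected, sign = sgn,
         groupA = seq_len(nPerGroup), groupB = nPerGroup + seq_len(nPerGroup))
}

#' Simulate the gene-expression surface coupled to promoter accessibility
#'
#' Per-gene log2 FPKM is baseline + coupling x accessibility score + the
#' gene's archetype offset per stage, where the score sums, over promoter
#' peaks present at a stage, (length / 500) x log2((normalized mean Tn5
#' count + 5) / 100) computed from the realized ATAC counts, so a planted
#' log2 intensity effect transmits symmetrically to log2 expression. Discordant
#' genes get a mean-preserving sign flip of the accessibility term. Raw
#' exon counts are NB-sampled from the target FPKM (count = FPKM x gene
#' length x library size / 1e9), and the reported FPKM is recomputed from
#' those counts so both surfaces are mutually consistent.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param acrSim Output of [simulateACRs()].
#' @param atacCounts Matrix from [simulateCounts()].
#' @param config A [SimConfig-class].
#' @return list(fpkm, counts = gene x sample matrices, geneLengths = named
#'   vector, baseline = named per-gene baseline log2 FPKM).
#' @export
simulateExpression <- function(annotation, acrSim, atacCounts, config) {
    set.seed(config@seed * 1000 + 4)
    genes <- geneModels(annotation)
    gids <- genes$gene_id
    geneLen <- setNames(width(genes), gids)
    samples <- sampleNames()
    stages <- acrStages()
    stageOf <- sampleStages(samples)
    p <- acrSim$basePeaks
    sf <- config@librarySizes / mean(config@librarySizes)
    norm <- sweep(atacCounts, 2, sf, "/")
    stageMeanCount <- vapply(stages, function(st)
        rowMeans(norm[, stageOf == st, drop = FALSE]),
        numeric(nrow(norm)))
    ## accessibility score per gene per stage
    score <- matrix(0, nrow = length(gids), ncol = 3,
                    dimnames = list(gids, stages))
    promRows <- which(!is.na(p$gene_id))
    for (i in promRows) {
        g <- p$gene_id[i]
        present <- if (p$label[i] == "shared") rep(TRUE, 3) else
            stages == p$stage[i]
        contrib <- (width(p)[i] / 500) *
            log2((stageMeanCount[p$peak_id[i], ] + 5) / 100)
        score[g, ] <- score[g, ] + ifelse(present, contrib, 0)
    }
    clusterOf <- setNames(acrSim$truth$geneClusters$cluster,
                          acrSim$truth$geneClusters$gene_id)
    discordant <- acrSim$truth$discordantGenes
    ## silent genes preferentially among genes without promoter peaks
    nSilent <- round(config@silentGeneFrac * length(gids))
    protected <- unique(c(names(clusterOf), discordant,
                          p$gene_id[promRows]))
    silentPool <- setdiff(gids, protected)
    silent <- if (nSilent > 0)
        sample(silentPool, min(nSilent, length(silentPool))) else
        character(0)
    baseline <- setNames(rnorm(length(gids), 3.5, 1.0), gids)
    mu <- matrix(rep(baseline, 3), ncol = 3,
                 dimnames = list(gids, stages))
    cpl <- config@expressionCoupling
    term <- cpl * score
    if (length(discordant)) {
        m <- rowMeans(score[discordant, , drop = FALSE])
        term[discordant, ] <- cpl *
            (2 * m - score[discordant, , drop = FALSE])
    }
    mu <- mu + term
    if (length(clusterOf))
        mu[names(clusterOf), ] <- mu[names(clusterOf), ] +
            config@clusterArchetypes[clusterOf, , drop = FALSE]
    fpkm <- counts <- matrix(0, nrow = length(gids), ncol = length(samples),
                             dimnames = list(gids, samples))
    for (s in seq_along(samples)) {
        x <- mu[, stageOf[s]] + rnorm(length(gids), 0,
                                      config@expressionNoiseSd)
        targetFpkm <- 2^x
        targetFpkm[silent] <- 0
        meanCount <- targetFpkm * geneLen *
            config@rnaLibrarySizes[s] / 1e9
        cnt <- rnbinom(length(gids), mu = meanCount,
                       size = 1 / config@nbDispersion)
        counts[, s] <- cnt
        fpkm[, s] <- 1e9 * cnt / (geneLen * config@rnaLibrarySizes[s])
    }
    list(fpkm = fpkm, counts = counts, geneLengths = geneLen,
         baseline = baseline, silent = silent)
}

#' Simulate Tn5 fragment files
#'
#' Per sample, fragment midpoints are a mixture of uniform background
#' (weight `backgroundFragmentFrac`) and peak-centered normals (sd = peak
#' length / 4) weighted by the peak's realized count in that sample, with
#' promoter (TSS-proximal) peaks up-weighted 2x.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param acrSim Output of [simulateACRs()].
#' @param atacCounts Matrix from [simulateCounts()].
#' @param config A [SimConfig-class].
#' @param tssWeight Extra weight for promoter peaks (default 2).
#' @return Named list (sample -> GRanges of fragments, ~80 bp).
#' @export
simulateFragments <- function(annotation, acrSim, atacCounts, config,
                              tssWeight = 2) {
    set.seed(config@seed * 1000 + 5)
    cs <- chromSizes(annotation)
    p <- acrSim$basePeaks
    mid <- classificationPositions(p)
    pchrom <- as.character(seqnames(p))
    samples <- sampleNames()
    out <- list()
    nFrag <- config@fragmentsPerSample
    nBg <- round(config@backgroundFragmentFrac * nFrag)
    for (s in samples) {
        w <- atacCounts[, s] * ifelse(p$category == "promoter", tssWeight, 1)
        nPk <- nFrag - nBg
        pkIdx <- sample.int(length(p), nPk, replace = TRUE,
                            prob = pmax(w, 1e-9))
        pkMid <- as.integer(round(rnorm(nPk, mid[pkIdx],
                                        width(p)[pkIdx] / 4)))
        pkChrom <- pchrom[pkIdx]
        bgChrom <- names(cs)[sample.int(length(cs), nBg, replace = TRUE,
                                        prob = cs / sum(cs))]
        bgMid <- as.integer(1 + floor(runif(nBg) * cs[bgChrom]))
        chrom <- c(pkChrom, bgChrom)
        m <- c(pkMid, bgMid)
        m <- pmax(41L, pmin(m, cs[chrom] - 41L))
        gr <- GRanges(chrom, IRanges(m - 40L, m + 39L))
        out[[s]] <- gr[order(as.character(seqnames(gr)), start(gr))]
    }
    out
}

#' Simulate the genome sequence with planted promoter motifs
#'
#' Random uniform sequence; the first consensus motif is embedded inside
#' the promoter peaks of archetype-C1 genes and the second (when given)
#' inside those of archetype-C7 genes, in `motifTargetFrac` of the
#' candidate promoters.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param acrSim Output of [simulateACRs()].
#' @param config A [SimConfig-class].
#' @return list(genome = DNAStringSet, placements = data.frame(gene_id,
#'   peak_id, motif, offset relative to peak start)).
#' @export
simulateSequences <- function(annotation, acrSim, config) {
    set.seed(config@seed * 1000 + 6)
    cs <- chromSizes(annotation)
    genome <- DNAStringSet(vapply(names(cs), function(ch)
        paste(sample(c("A", "C", "G", "T"), cs[ch], replace = TRUE),
              collapse = ""), ""))
    names(genome) <- names(cs)
    p <- acrSim$basePeaks
    clusterOf <- setNames(acrSim$truth$geneClusters$cluster,
                          acrSim$truth$geneClusters$gene_id)
    targetsFor <- c(1L, 7L)
    placements <- list()
    seqs <- as.list(as.character(genome))
    for (mi in seq_along(config@motifConsensus)) {
        if (mi > length(targetsFor)) break
        motif <- config@motifConsensus[mi]
        cgenes <- names(clusterOf)[clusterOf == targetsFor[mi]]
        cand <- which(!is.na(p$gene_id) & p$gene_id %in% cgenes &
                      p$category == "promoter")
        if (!length(cand)) next
        nPlant <- round(config@motifTargetFrac * length(cand))
        chosen <- if (nPlant > 0) sample(cand, nPlant) else integer(0)
        for (i in chosen) {
            len <- nchar(motif)
            maxOff <- width(p)[i] - len - 10L
            if (maxOff < 10L) next
            off <- sample(10:maxOff, 1)
            abs0 <- start(p)[i] + off
            ch <- as.character(seqnames(p)[i])
            substr(seqs[[ch]], abs0, abs0 + len - 1L) <- motif
            placements[[length(placements) + 1]] <- data.frame(
                gene_id = p$gene_id[i], peak_id = p$peak_id[i],
                motif = motif, offset = off)
        }
    }
    genome <- DNAStringSet(unlist(seqs))
    names(genome) <- names(cs)
    list(genome = genome,
         placements = if (length(placements)) do.call(rbind, placements)
         else data.frame(gene_id = character(0), peak_id = character(0),
                         motif = character(0), offset = integer(0)))
}

#' Generate a complete synthetic dataset
#'
#' Runs all sub-generators (genome, ACR landscape, counts, expression,
#' fragments, sequence) under a documented seed-splitting scheme (stream k
#' uses seed x 1000 + k) and assembles the [TruthSet-class]. When `outdir`
#' is given, all standard files are written: GFF3 + chrom.sizes, one
#' narrowPeak per stage/replicate, ATAC count TSV, FPKM and exon-count
#' TSVs, fragment BEDs, genome FASTA and the truth JSON.
#'
#' @param config A [SimConfig-class].
#' @param outdir Optional output directory (created if missing).
#' @param sequences Also simulate the genome sequence (default TRUE).
#' @return list(config, annotation, basePeaks, stageRepPeaks, atacCounts,
#'   expression, fragments, genome, motifPlacements, truth).
#' @export
simulateDataset <- function(config, outdir = NULL, sequences = TRUE) {
    annotation <- simulateGenome(config)
    acrSim <- simulateACRs(annotation, config)
    atacCounts <- simulateCounts(acrSim, config)
    expression <- simulateExpression(annotation, acrSim, atacCounts, config)
    fragments <- simulateFragments(annotation, acrSim, atacCounts, config)
    seqSim <- if (sequences) simulateSequences(annotation, acrSim, config)
        else list(genome = DNAStringSet(), placements = data.frame(
            gene_id = character(0), peak_id = character(0),
            motif = character(0), offset = integer(0)))
    truth <- new("TruthSet",
                 peakLabels = acrSim$truth$peakLabels,
                 dpiEffects = acrSim$truth$dpiEffects,
                 peakGene = acrSim$truth$peakGene,
                 geneClusters = acrSim$truth$geneClusters,
                 discordantGenes = acrSim$truth$discordantGenes,
                 motifPlacements = seqSim$placements)
    sim <- list(config = config, annotation = annotation,
                basePeaks = acrSim$basePeaks,
                stageRepPeaks = acrSim$stageRepPeaks,
                atacCounts = atacCounts, expression = expression,
                fragments = fragments, genome = seqSim$genome,
                truth = truth)
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        writeAnnotationGFF3(annotation, file.path(outdir, "annotation.gff3"))
        writeChromSizes(chromSizes(annotation),
                        file.path(outdir, "chrom.sizes"))
        for (st in names(sim$stageRepPeaks))
            for (rp in names(sim$stageRepPeaks[[st]]))
                writePeaks(sim$stageRepPeaks[[st]][[rp]],
                           file.path(outdir, paste0("peaks_", st, "_", rp,
                                                    ".narrowPeak")),
                           format = "narrowPeak")
        writeMatrixTSV(atacCounts, file.path(outdir, "atac_counts.tsv"))
        writeMatrixTSV(expression$fpkm, file.path(outdir, "fpkm.tsv"))
        writeMatrixTSV(expression$counts,
                       file.path(outdir, "exon_counts.tsv"))
        for (s in names(fragments))
            writeFragments(fragments[[s]],
                           file.path(outdir, paste0("fragments_", s,
                                                    ".bed")))
        if (length(seqSim$genome))
            writeXStringSet(seqSim$genome, file.path(outdir, "genome.fa"))
        writeTruthSet(truth, file.path(outdir, "truth.json"))
    }
    sim
}
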