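#' Assign ACRs to genes through promoter windows
#'
#' An ACR is assigned to a gene when its classification position (summit, or
#' midpoint without one) falls inside the gene's promoter window. An ACR
#' lying in overlapping promoter windows of several genes goes to the gene
#' with the nearest TSS; exact distance ties are assigned to all tied genes
#' and flagged `ambiguous`.
#'
#' @param acrs GRanges of ACRs (metadata `peak_id` recommended).
#' @param annotation A GenomeAnnotation.
#' @param promoterWidth Promoter window width in bp (default 2000).
#' @param intensity Optional named numeric vector (peak id -> intensity) to
#'   carry through.
#' @return data.frame: gene_id, peak_id, length, intensity (NA when not
#'   supplied), ambiguous.
#' @export
assignPromoterACRs <- function(acrs, annotation, promoterWidth = 2000,
                               intensity = NULL) {
    empty <- data.frame(gene_id = character(0), peak_id = character(0),
                        length = integer(0), intensity = numeric(0),
                        ambiguous = logical(0))
    if (!length(acrs)) return(empty)
    prom <- promoterWindows(annotation, promoterWidth)
    if (!length(prom)) return(empty)
    ids <- peakIds(acrs)
    pos <- classificationPositions(acrs)
    pts <- GRanges(seqnames(acrs), IRanges(pos, pos))
    hits <- findOverlaps(pts, prom, ignore.strand = TRUE)
    if (!length(hits)) return(empty)
    tss <- tssPositions(annotation)
    q <- queryHits(hits); s <- subjectHits(hits)
    dist <- abs(pos[q] - tss[prom$gene_id[s]])
    keep <- logical(length(hits))
    ambiguous <- logical(length(hits))
    for (pk in unique(q)) {
        rows <- which(q == pk)
        best <- min(dist[rows])
        winners <- rows[dist[rows] == best]
        keep[winners] <- TRUE
        if (length(winners) > 1) ambiguous[winners] <- TRUE
    }
    out <- data.frame(gene_id = prom$gene_id[s[keep]],
                      peak_id = ids[q[keep]],
                      length = width(acrs)[q[keep]],
                      intensity = if (is.null(intensity)) NA_real_ else
                          unname(intensity[ids[q[keep]]]),
                      ambiguous = ambiguous[keep],
                      row.names = NULL)
    out[order(out$gene_id, out$peak_id), , drop = FALSE]
}

#' Expression compared across promoter-ACR count groups
#'
#' Genes are partitioned by the number of promoter ACRs (groups 0, 1, 2,
#' 3+); adjacent groups are compared with a two-sided rank test and group
#' medians reported.
#'
#' @param assignment data.frame from [assignPromoterACRs()].
#' @param fpkm Named numeric vector of expression values; its names define
#'   the gene universe (genes absent from `assignment` count as 0 ACRs).
#' @return list(groups = named list of gene ids, medians, tests =
#'   data.frame of adjacent-pair p-values, counts).
#' @export
expressionByACRCount <- function(assignment, fpkm) {
    nACR <- table(assignment$gene_id)
    cnt <- setNames(rep(0L, length(fpkm)), names(fpkm))
    known <- intersect(names(nACR), names(cnt))
    cnt[known] <- as.integer(nACR[known])
    lab <- ifelse(cnt >= 3, "3+", as.character(cnt))
    labels <- c("0", "1", "2", "3+")
    groups <- lapply(labels, function(l) names(cnt)[lab == l])
    names(groups) <- labels
    medians <- vapply(groups, function(g)
        if (length(g)) median(fpkm[g]) else NA_real_, 1)
    tests <- data.frame(comparison = character(0), p = numeric(0))
    for (i in seq_len(length(labels) - 1)) {
        g1 <- groups[[i]]; g2 <- groups[[i + 1]]
        if (length(g1) >= 2 && length(g2) >= 2) {
            p <- rankTest(fpkm[g1], fpkm[g2])
            tests <- rbind(tests, data.frame(
                comparison = paste(labels[i], "vs", labels[i + 1]), p = p))
        }
    }
    list(groups = groups, medians = medians, tests = tests,
         counts = vapply(groups, length, 1L))
}

#' Length tertiles of single-ACR promoters with balanced ties
#'
#' Genes with exactly one promoter ACR are sorted by ACR length (descending,
#' ties broken by gene id) and split into top/middle/bottom groups of
#' near-equal size. Runs of equal length straddling a group boundary are
#' distributed round-robin across the groups they straddle, so similar-length
#' ACRs are balanced between groups. Expression of top vs bottom is compared
#' with a two-sided rank test.
#'
#' @param assignment data.frame from [assignPromoterACRs()].
#' @param fpkm Named numeric vector of expression values.
#' @return list(groups = list(top, middle, bottom) of gene ids, medians,
#'   p_top_vs_bottom).
#' @export
lengthTertiles <- function(assignment, fpkm) {
    tab <- table(assignment$gene_id)
    single <- names(tab)[tab == 1]
    sub <- assignment[assignment$gene_id %in% single, , drop = FALSE]
    sub <- sub[sub$gene_id %in% names(fpkm), , drop = FALSE]
    n <- nrow(sub)
    if (n < 3) stop("need >= 3 single-ACR genes to form tertiles")
    ord <- order(-sub$length, sub$gene_id)
    sub <- sub[ord, , drop = FALSE]
    sizes <- rep(n %/% 3, 3)
    extra <- n %% 3
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    provisional <- rep(1:3, times = sizes)
    grp <- provisional
    runs <- rle(sub$length)
    stop_ <- cumsum(runs$lengths)
    start_ <- stop_ - runs$lengths + 1L
    for (j in seq_along(runs$lengths)) {
        idx <- start_[j]:stop_[j]
        gset <- unique(provisional[idx])
        if (length(gset) > 1) {
            slots <- unlist(lapply(gset, function(g)
                rep(g, sum(provisional[idx] == g))))
            ## interleave members across the straddled groups
            grp[idx] <- unlist(split(slots, seq_along(slots) %%
                                     length(gset)))[seq_along(idx)]
        }
    }
    groups <- list(top = sub$gene_id[grp == 1],
                   middle = sub$gene_id[grp == 2],
                   bottom = sub$gene_id[grp == 3])
    medians <- vapply(groups, function(g) median(fpkm[g]), 1)
    p <- if (length(groups$top) >= 2 && length(groups$bottom) >= 2)
        rankTest(fpkm[groups$top], fpkm[groups$bottom]) else NA_real_
    list(groups = groups, medians = medians, p_top_vs_bottom = p)
}

#' ACR association classes across expression bins
#'
#' Genes are split into six expression groups: no expression (FPKM = 0) and
#' five quintiles of the expressed genes (group 1 = lowest 20%, group 5 =
#' highest 20%). Each gene is classified by where its ACRs sit: promoter
#' only, gene body only, both, or none; per-group proportions sum to 1.
#'
#' @param acrs GRanges of ACRs.
#' @param annotation A GenomeAnnotation.
#' @param fpkm Named numeric vector of expression values (gene universe).
#' @param promoterWidth Promoter window width in bp.
#' @return list(table = 6 x 4 proportion matrix, counts = group sizes,
#'   classes = named character of per-gene class).
#' @export
acrAssociationByExpressionBin <- function(acrs, annotation, fpkm,
                                          promoterWidth = 2000) {
    genes <- names(fpkm)
    assignment <- assignPromoterACRs(acrs, annotation, promoterWidth)
    promGenes <- unique(assignment$gene_id)
    g <- geneModels(annotation)
    g <- g[g$gene_id %in% genes]
    bodyHit <- countOverlaps(g, acrs, ignore.strand = TRUE) > 0
    bodyGenes <- g$gene_id[bodyHit]
    cls <- setNames(rep("none", length(genes)), genes)
    cls[genes %in% promGenes & genes %in% bodyGenes] <- "both"
    cls[genes %in% promGenes & !(genes %in% bodyGenes)] <- "promoter_only"
    cls[!(genes %in% promGenes) & genes %in% bodyGenes] <- "body_only"
    expressed <- genes[fpkm > 0]
    bin <- setNames(rep("0", length(genes)), genes)
    if (length(expressed)) {
        r <- rank(fpkm[expressed], ties.method = "first")
        q <- ceiling(5 * r / length(expressed))
        bin[expressed] <- as.character(q)
    }
    binLevels <- c("0", "1", "2", "3", "4", "5")
    classLevels <- c("promoter_only", "body_only", "both", "none")
    tab <- matrix(0, nrow = 6, ncol = 4,
                  dimnames = list(binLevels, classLevels))
    for (b in binLevels) {
        inBin <- names(bin)[bin == b]
        if (length(inBin))
            tab[b, ] <- as.numeric(table(factor(cls[inBin],
                                                classLevels))) /
                length(inBin)
    }
    list(table = tab,
         counts = vapply(binLevels, function(b) sum(bin == b), 1L),
         classes = cls)
}

#' Two-sided two-sample rank test
#'
#' Wilcoxon rank-sum (Mann-Whitney) test: exact enumeration when the
#' combined sample size is at most `exactLimit` and there are no ties,
#' normal approximation with tie correction otherwise. Returns p = 1 when
#' all values across both samples are tied.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @param exactLimit Combined-size limit for exact enumeration (default 12).
#' @param correct Continuity correction for the normal approximation.
#' @return Two-sided p-value.
#' @export
rankTest <- function(x, y, exactLimit = 12, correct = TRUE) {
    stopifnot(length(x) >= 2, length(y) >= 2)
    if (length(unique(c(x, y))) == 1) return(1)
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) + length(y)) <= exactLimit && !ties
    suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = correct)$p.value)
}
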