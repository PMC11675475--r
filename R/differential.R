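#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of
#' count / geometric-mean(feature), computed on features with all-positive
#' counts, then rescaled so the factors have geometric mean 1. When no
#' feature is positive in every sample, falls back to library-size ratios
#' with a warning.
#'
#' @param counts Non-negative integer matrix (features x samples).
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
medianRatioSizeFactors <- function(counts) {
    counts <- as.matrix(counts)
    allPos <- rowSums(counts > 0) == ncol(counts)
    if (!any(allPos)) {
        warning("no feature with all-positive counts; ",
                "falling back to library-size ratios")
        sf <- colSums(counts)
        sf <- sf / mean(sf)
    } else {
        logGeo <- rowMeans(log(counts[allPos, , drop = FALSE]))
        sf <- apply(counts[allPos, , drop = FALSE], 2, function(col)
            median(exp(log(col) - logGeo)))
    }
    sf <- sf / exp(mean(log(sf)))
    setNames(sf, colnames(counts))
}

#' Negative-binomial Wald test between two sample groups
#'
#' A self-contained differential test for count features: median-of-ratios
#' normalization, per-feature method-of-moments dispersion shrunk toward a
#' log-linear mean-dispersion trend (geometric interpolation, weight
#' `shrink`), and a Wald test on the log2 fold change (group B over group A)
#' with a delta-method standard error. Benjamini-Hochberg adjustment is
#' applied across tested features; features with all-zero counts are
#' excluded from testing and from the BH denominator. A feature is
#' significant iff padj < `alpha` and |log2fc| > `lfcThreshold`.
#'
#' @param counts Non-negative integer matrix (features x samples).
#' @param groupA,groupB Column names or indices of the two groups
#'   (each >= 2 samples).
#' @param sizeFactors Optional per-sample factors for the used columns;
#'   estimated by [medianRatioSizeFactors()] when NULL.
#' @param dispersion Optional known NB dispersion (scalar or per-feature);
#'   when supplied the moment/trend estimation is skipped (the Poisson
#'   limit corresponds to dispersion -> 0).
#' @param shrink Weight of the per-feature estimate in the geometric
#'   interpolation with the trend (default 0.5).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param lfcThreshold Absolute log2 fold-change threshold (default 1).
#' @return data.frame: feature, baseMeanA, baseMeanB, log2fc, p, padj,
#'   significant, direction (up/down/ns; all-zero features get NA p and
#'   direction ns).
#' @export
nbTest <- function(counts, groupA, groupB, sizeFactors = NULL,
                   dispersion = NULL, shrink = 0.5, alpha = 0.05,
                   lfcThreshold = 1) {
    counts <- as.matrix(counts)
    A <- resolveColumns(counts, groupA)
    B <- resolveColumns(counts, groupB)
    if (length(A) < 2 || length(B) < 2)
        stop("each group needs >= 2 samples for a dispersion estimate")
    sub <- counts[, c(A, B), drop = FALSE]
    if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(sub)
    norm <- sweep(sub, 2, sizeFactors, "/")
    nA <- length(A); nB <- length(B)
    iA <- seq_len(nA); iB <- nA + seq_len(nB)
    tested <- rowSums(sub) > 0
    muA <- rowMeans(norm[, iA, drop = FALSE])
    muB <- rowMeans(norm[, iB, drop = FALSE])
    varA <- apply(norm[, iA, drop = FALSE], 1, var)
    varB <- apply(norm[, iB, drop = FALSE], 1, var)
    s2 <- ((nA - 1) * varA + (nB - 1) * varB) / (nA + nB - 2)
    mu <- (muA + muB) / 2
    dispFloor <- 1e-8
    if (!is.null(dispersion)) {
        disp <- pmax(rep_len(dispersion, nrow(sub)), dispFloor)
    } else {
        alphaRaw <- ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)
        fitIdx <- which(tested & !is.na(alphaRaw) & alphaRaw > 0 & mu > 0)
        if (length(fitIdx) >= 10) {
            fit <- lm(log(alphaRaw[fitIdx]) ~ log(mu[fitIdx]))
            alphaTrend <- exp(coef(fit)[1] +
                              coef(fit)[2] * log(pmax(mu, 1e-8)))
        } else {
            alphaTrend <- rep(if (length(fitIdx))
                exp(mean(log(alphaRaw[fitIdx]))) else 0.01, nrow(sub))
        }
        alphaTrend <- pmax(alphaTrend, dispFloor)
        disp <- ifelse(!is.na(alphaRaw) & alphaRaw > 0,
                       exp(shrink * log(pmax(alphaRaw, dispFloor)) +
                           (1 - shrink) * log(alphaTrend)),
                       alphaTrend)
        disp <- pmax(disp, dispFloor)
    }
    eps <- 0.5
    needPseudo <- muA == 0 | muB == 0
    lfc <- ifelse(needPseudo,
                  log2((muB + eps) / (muA + eps)),
                  log2(muB / muA))
    vA <- (1 / pmax(muA, eps) + disp) / nA
    vB <- (1 / pmax(muB, eps) + disp) / nB
    se <- sqrt(vA + vB) / log(2)
    z <- lfc / se
    p <- 2 * pnorm(-abs(z))
    p[!tested] <- NA_real_
    lfc[!tested] <- 0
    padj <- rep(NA_real_, length(p))
    padj[tested] <- p.adjust(p[tested], method = "BH")
    significant <- !is.na(padj) & padj < alpha & abs(lfc) > lfcThreshold
    direction <- ifelse(significant, ifelse(lfc > 0, "up", "down"), "ns")
    data.frame(feature = rownames(counts) %||%
                   paste0("feature_", seq_len(nrow(counts))),
               baseMeanA = muA, baseMeanB = muB, log2fc = lfc,
               p = p, padj = padj, significant = significant,
               direction = direction, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolveColumns <- function(counts, idx) {
    if (is.character(idx)) match(idx, colnames(counts)) else as.integer(idx)
}

#' Differentially expressed genes across all stage pairs
#'
#' Applies [nbTest()] to each pairwise stage comparison and returns the
#' per-comparison results together with the union of significant genes.
#'
#' @param counts Gene-level count matrix (genes x samples).
#' @param stages Character vector of stage labels, one per column.
#' @param genes Optional subset of gene ids to test (e.g. the
#'   [filterExpressed()] set).
#' @param ... Passed to [nbTest()].
#' @return list(results = named list of per-comparison data.frames,
#'   union = character vector of genes significant in >= 1 comparison).
#' @export
identifyDEGs <- function(counts, stages, genes = NULL, ...) {
    counts <- as.matrix(counts)
    if (!is.null(genes))
        counts <- counts[rownames(counts) %in% genes, , drop = FALSE]
    stageLevels <- unique(stages)
    pairs <- utils::combn(stageLevels, 2, simplify = FALSE)
    results <- list()
    for (pr in pairs) {
        lab <- paste(pr[1], "vs", pr[2])
        results[[lab]] <- nbTest(counts,
                                 groupA = which(stages == pr[1]),
                                 groupB = which(stages == pr[2]), ...)
    }
    sig <- lapply(results, function(r) r$feature[r$significant])
    list(results = results, union = sort(unique(unlist(sig))))
}

#' Expressed-gene filter on an FPKM table
#'
#' Default rule: retain genes with FPKM > `threshold` in all replicates of
#' at least one stage. The alternative rule retains genes with FPKM >
#' `threshold` in at least three samples overall.
#'
#' @param fpkm Numeric matrix (genes x samples).
#' @param stages Character vector of stage labels, one per column.
#' @param rule `"allRepsOneStage"` (default) or `"threeSamplesTotal"`.
#' @param threshold FPKM threshold (default 1).
#' @return Character vector of retained gene ids.
#' @export
filterExpressed <- function(fpkm, stages,
                            rule = c("allRepsOneStage", "threeSamplesTotal"),
                            threshold = 1) {
    rule <- match.arg(rule)
    fpkm <- as.matrix(fpkm)
    keep <- if (rule == "allRepsOneStage") {
        byStage <- vapply(unique(stages), function(s)
            rowSums(fpkm[, stages == s, drop = FALSE] > threshold) ==
                sum(stages == s), logical(nrow(fpkm)))
        rowSums(matrix(byStage, nrow = nrow(fpkm))) > 0
    } else {
        rowSums(fpkm > threshold) >= 3
    }
    rownames(fpkm)[keep]
}

#' Per-gene correlation between promoter ACR intensity and expression
#'
#' For each gene with assigned promoter peaks, computes the Pearson r across
#' stages between the summed stage-level peak intensity of its promoter
#' ACRs and its stage-level expression. Genes with zero variance in either
#' vector are excluded from the summaries.
#'
#' @param peakIntensity Numeric matrix (peak id x stage) of normalized mean
#'   peak intensities.
#' @param expression Numeric matrix (gene id x stage) of stage-level
#'   expression (e.g. mean FPKM).
#' @param assignment data.frame with columns `gene_id`, `peak_id` (e.g. from
#'   [assignPromoterACRs()]).
#' @param genes Optional subset of genes to summarize (e.g. genes whose
#'   promoter peak is a significant DPI).
#' @return list(perGene = data.frame(gene_id, r), fraction_positive,
#'   median_r, n).
#' @export
intensityExpressionCorrelation <- function(peakIntensity, expression,
                                           assignment, genes = NULL) {
    if (ncol(peakIntensity) < 2 || ncol(expression) < 2)
        stop("need >= 2 stages for a correlation")
    gset <- unique(assignment$gene_id)
    if (!is.null(genes)) gset <- intersect(gset, genes)
    gset <- intersect(gset, rownames(expression))
    rs <- vapply(gset, function(g) {
        pk <- assignment$peak_id[assignment$gene_id == g]
        pk <- pk[pk %in% rownames(peakIntensity)]
        if (!length(pk)) return(NA_real_)
        ivec <- colSums(peakIntensity[pk, , drop = FALSE])
        evec <- expression[g, ]
        if (sd(ivec) == 0 || sd(evec) == 0) return(NA_real_)
        cor(ivec, evec)
    }, 1)
    ok <- !is.na(rs)
    list(perGene = data.frame(gene_id = gset, r = unname(rs),
                              row.names = NULL),
         fraction_positive = if (any(ok)) mean(rs[ok] > 0) else NA_real_,
         median_r = if (any(ok)) median(rs[ok]) else NA_real_,
         n = sum(ok))
}
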