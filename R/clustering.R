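#' Cluster DEGs into stage-pattern archetypes
#'
#' Per-gene stage means of log2(FPKM + 1) are z-scored and clustered with
#' seeded multi-start k-means (best inertia over `nstart` starts). When
#' archetype patterns are supplied, clusters are relabeled deterministically
#' so that each cluster takes the label of its nearest archetype (greedy
#' one-to-one matching on centroid distance).
#'
#' @param fpkm Numeric matrix (genes x samples).
#' @param stages Character stage label per column.
#' @param genes Gene ids to cluster (typically the DEG union).
#' @param k Number of clusters (default 8).
#' @param seed Integer seed for the k-means starts.
#' @param archetypes Optional k x nStages matrix of stage-level patterns
#'   (rownames = labels C1..Ck).
#' @param nstart Number of k-means starts (default 10).
#' @return list(assignment = named integer cluster per gene, centroids =
#'   k x nStages matrix of z-scored centroids, stageMeans = z-scored input).
#' @export
clusterDEGs <- function(fpkm, stages, genes, k = 8, seed = 1,
                        archetypes = NULL, nstart = 10) {
    fpkm <- as.matrix(fpkm)
    genes <- intersect(genes, rownames(fpkm))
    if (length(genes) < k)
        stop("fewer genes than clusters")
    stageLevels <- unique(stages)
    sm <- vapply(stageLevels, function(s)
        rowMeans(log2(fpkm[genes, stages == s, drop = FALSE] + 1)),
        numeric(length(genes)))
    z <- t(apply(sm, 1, zscore))
    dimnames(z) <- list(genes, stageLevels)
    set.seed(seed)
    km <- kmeans(z, centers = k, nstart = nstart, iter.max = 50)
    if (!is.null(archetypes)) {
        ## an archetype-initialized run guards against local optima that
        ## merge adjacent patterns; the best-inertia solution wins
        za0 <- t(apply(archetypes, 1, zscore))
        kmA <- try(kmeans(z, centers = za0, iter.max = 50), silent = TRUE)
        if (!inherits(kmA, "try-error") &&
            kmA$tot.withinss < km$tot.withinss)
            km <- kmA
    }
    assignment <- setNames(km$cluster, genes)
    centroids <- km$centers
    if (!is.null(archetypes)) {
        za <- t(apply(archetypes, 1, zscore))
        map <- greedyMatch(centroids, za)
        relabeled <- map[assignment]
        assignment <- setNames(as.integer(relabeled), genes)
        centroids <- centroids[order(map), , drop = FALSE]
        rownames(centroids) <- paste0("C", seq_len(k))
    }
    list(assignment = assignment, centroids = centroids, stageMeans = z)
}

zscore <- function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

## Greedy one-to-one assignment of centroids (rows of a) to archetypes
## (rows of b) by increasing Euclidean distance; ties resolved by row order.
greedyMatch <- function(a, b) {
    d <- as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                             nrow(a) + seq_len(nrow(b))]
    map <- integer(nrow(a))
    usedA <- usedB <- logical(nrow(a))
    for (step in seq_len(nrow(a))) {
        d2 <- d
        d2[usedA, ] <- Inf
        d2[, usedB] <- Inf
        idx <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
        map[idx[1]] <- idx[2]
        usedA[idx[1]] <- TRUE
        usedB[idx[2]] <- TRUE
    }
    map
}

#' Fisher enrichment of gene sets across expression clusters
#'
#' For each (gene set, cluster) pair, builds the 2x2 table over the
#' universe and reports the overlap count, the overlap proportion of the
#' set, and the one-sided (enrichment) Fisher exact p-value.
#'
#' @param geneSets Named list of character vectors (e.g. stage-specific-ACR
#'   genes per stage); each is intersected with the universe first.
#' @param clusters Named integer vector gene -> cluster label.
#' @param universe Character vector, the gene universe (e.g. the DEG union).
#' @param twoSided Use a two-sided Fisher test instead (default FALSE).
#' @return data.frame: set, cluster, overlap, set_size, cluster_size,
#'   proportion, p.
#' @export
clusterOverlapFisher <- function(geneSets, clusters, universe,
                                 twoSided = FALSE) {
    N <- length(unique(universe))
    clusters <- clusters[names(clusters) %in% universe]
    out <- list()
    for (sname in names(geneSets)) {
        set <- intersect(geneSets[[sname]], universe)
        n <- length(set)
        for (cl in sort(unique(clusters))) {
            inCl <- names(clusters)[clusters == cl]
            K <- length(inCl)
            k <- length(intersect(set, inCl))
            p <- if (n == 0) 1 else if (twoSided)
                fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2))$
                    p.value
            else
                phyper(k - 1, K, N - K, n, lower.tail = FALSE)
            out[[length(out) + 1]] <- data.frame(
                set = sname, cluster = cl, overlap = k, set_size = n,
                cluster_size = K,
                proportion = if (n > 0) k / n else 0, p = p)
        }
    }
    do.call(rbind, out)
}

#' Integrate promoter DPI with DEG direction into quadrant counts
#'
#' For each stage-pair comparison, every gene with at least one significant
#' promoter DPI peak and a significant DEG call is placed in one of four
#' quadrants by the signs of the peak and gene log2 fold changes. Genes
#' whose significant promoter peaks disagree in sign are excluded and
#' reported.
#'
#' @param dpiResults Named list of [nbTest()] data.frames on peaks, one per
#'   comparison.
#' @param assignment data.frame (gene_id, peak_id) from
#'   [assignPromoterACRs()].
#' @param degResults Named list of [nbTest()] data.frames on genes with the
#'   same comparison names.
#' @return Named list per comparison: list(quadrants = named integer counts
#'   (atac_up_rna_up, atac_down_rna_down, atac_up_rna_down,
#'   atac_down_rna_up), genes = named list of gene ids per quadrant,
#'   conflicting = excluded gene ids).
#' @export
integrateDPIDEG <- function(dpiResults, assignment, degResults) {
    if (!setequal(names(dpiResults), names(degResults)))
        stop("comparison labels differ between DPI and DEG results")
    quadNames <- c("atac_up_rna_up", "atac_down_rna_down",
                   "atac_up_rna_down", "atac_down_rna_up")
    out <- list()
    for (cmp in names(dpiResults)) {
        dpi <- dpiResults[[cmp]]
        deg <- degResults[[cmp]]
        sigPeaks <- dpi[dpi$significant, , drop = FALSE]
        rows <- assignment[assignment$peak_id %in% sigPeaks$feature, ,
                           drop = FALSE]
        atacSign <- tapply(
            sign(sigPeaks$log2fc[match(rows$peak_id, sigPeaks$feature)]),
            rows$gene_id, function(s) if (length(unique(s)) == 1)
                unique(s) else NA_real_)
        conflicting <- names(atacSign)[is.na(atacSign)]
        atacSign <- atacSign[!is.na(atacSign)]
        sigDeg <- deg[deg$significant, , drop = FALSE]
        rnaSign <- setNames(sign(sigDeg$log2fc), sigDeg$feature)
        genes <- intersect(names(atacSign), names(rnaSign))
        quadOf <- function(a, r) {
            if (a > 0 && r > 0) "atac_up_rna_up"
            else if (a < 0 && r < 0) "atac_down_rna_down"
            else if (a > 0) "atac_up_rna_down"
            else "atac_down_rna_up"
        }
        quad <- vapply(genes, function(g)
            quadOf(atacSign[g], rnaSign[g]), "")
        counts <- setNames(integer(4), quadNames)
        tab <- table(factor(quad, quadNames))
        counts[names(tab)] <- as.integer(tab)
        out[[cmp]] <- list(
            quadrants = counts,
            genes = lapply(setNames(quadNames, quadNames), function(q)
                genes[quad == q]),
            conflicting = conflicting)
    }
    out
}

#' Hypergeometric term enrichment of a gene set
#'
#' One-sided hypergeometric (equivalently one-sided Fisher) enrichment of a
#' target set against annotated term sets within a universe. Terms with no
#' annotated gene in the universe are skipped. A BH-adjusted column is
#' reported, but the significance flag uses the raw p threshold.
#'
#' @param target Character vector, subset of `universe`.
#' @param universe Character vector of all considered genes.
#' @param termMap Named list term -> character vector of annotated genes.
#' @param alpha Raw-p significance threshold (default 0.05).
#' @return data.frame: term, overlap, set_size, annotated, universe_size,
#'   p, padj, significant.
#' @export
setEnrichment <- function(target, universe, termMap, alpha = 0.05) {
    if (!all(target %in% universe))
        stop("target must be a subset of the universe")
    N <- length(unique(universe))
    n <- length(unique(target))
    rows <- list()
    for (term in names(termMap)) {
        ann <- intersect(termMap[[term]], universe)
        K <- length(ann)
        if (K == 0) next
        k <- length(intersect(target, ann))
        p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
            term = term, overlap = k, set_size = n, annotated = K,
            universe_size = N, p = p)
    }
    if (!length(rows))
        return(data.frame(term = character(0), overlap = integer(0),
                          set_size = integer(0), annotated = integer(0),
                          universe_size = integer(0), p = numeric(0),
                          padj = numeric(0), significant = logical(0)))
    out <- do.call(rbind, rows)
    out$padj <- p.adjust(out$p, method = "BH")
    out$significant <- out$p < alpha
    out
}

#' Consensus-motif enrichment in target versus background sequences
#'
#' A sequence is a hit for a motif when the IUPAC consensus (or its reverse
#' complement) matches at any offset with at most `maxMismatch` mismatches.
#' Hit counts in target vs background sequences are compared with a
#' one-sided Fisher exact test.
#'
#' @param targetSeqs,backgroundSeqs DNAStringSet (or character) sequences.
#' @param motifs Character vector of IUPAC consensus motifs.
#' @param maxMismatch Allowed mismatches (default 0).
#' @param alpha Significance threshold on raw p (default 0.01).
#' @return data.frame: motif, target_hits, target_n, background_hits,
#'   background_n, p, significant. Motifs longer than every sequence are
#'   skipped with a warning.
#' @export
motifEnrichment <- function(targetSeqs, backgroundSeqs, motifs,
                            maxMismatch = 0, alpha = 0.01) {
    targetSeqs <- DNAStringSet(targetSeqs)
    backgroundSeqs <- DNAStringSet(backgroundSeqs)
    maxLen <- max(c(Biostrings::width(targetSeqs),
                    Biostrings::width(backgroundSeqs)))
    rows <- list()
    for (m in motifs) {
        if (nchar(m) > maxLen) {
            warning("motif ", m, " longer than every sequence; skipped")
            next
        }
        th <- motifHits(m, targetSeqs, maxMismatch)
        bh <- motifHits(m, backgroundSeqs, maxMismatch)
        tab <- matrix(c(sum(th), sum(!th), sum(bh), sum(!bh)), nrow = 2)
        p <- fisher.test(tab, alternative = "greater")$p.value
        rows[[length(rows) + 1]] <- data.frame(
            motif = m, target_hits = sum(th), target_n = length(th),
            background_hits = sum(bh), background_n = length(bh), p = p)
    }
    if (!length(rows))
        return(data.frame(motif = character(0), target_hits = integer(0),
                          target_n = integer(0),
                          background_hits = integer(0),
                          background_n = integer(0), p = numeric(0),
                          significant = logical(0)))
    out <- do.call(rbind, rows)
    out$significant <- out$p < alpha
    out
}

#' @rdname motifEnrichment
#' @param motif Single IUPAC consensus string.
#' @param seqs DNAStringSet to scan.
#' @return `motifHits`: logical vector, one per sequence.
#' @export
motifHits <- function(motif, seqs, maxMismatch = 0) {
    fwd <- vcountPattern(DNAString(motif), seqs,
                         max.mismatch = maxMismatch, fixed = FALSE)
    rev <- vcountPattern(reverseComplement(DNAString(motif)), seqs,
                         max.mismatch = maxMismatch, fixed = FALSE)
    (fwd + rev) > 0
}

#' Extract sequences under genomic regions
#'
#' @param genome DNAStringSet named by chromosome.
#' @param regions GRanges (clipped to chromosome bounds).
#' @return DNAStringSet, one sequence per region, named by `peak_id` when
#'   present.
#' @export
extractRegionSequences <- function(genome, regions) {
    chrom <- as.character(seqnames(regions))
    lens <- setNames(Biostrings::width(genome), names(genome))
    s <- pmax(start(regions), 1L)
    e <- pmin(end(regions), lens[chrom])
    out <- DNAStringSet(vapply(seq_along(regions), function(i)
        as.character(subseq(genome[[chrom[i]]], s[i], e[i])), ""))
    names(out) <- if (!is.null(regions$peak_id)) regions$peak_id else
        paste0("region_", seq_along(regions))
    out
}
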