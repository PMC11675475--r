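## Small fixtures and independent oracles shared across test files.

suppressPackageStartupMessages({
    library(GenomicRanges)
})

## Two-chromosome toy annotation with three genes (two +, one -), built by
## hand so expected categories/windows are known exactly.
toyAnnotation <- function() {
    genes <- GRanges(c("chrA", "chrA", "chrB"),
                     IRanges(c(5001, 12001, 4001), c(7000, 14000, 6000)),
                     strand = c("+", "-", "+"))
    genes$gene_id <- c("g1", "g2", "g3")
    exons <- GRanges(c("chrA", "chrA", "chrA", "chrA", "chrB"),
                     IRanges(c(5001, 6501, 12001, 13501, 4001),
                             c(5800, 7000, 12800, 14000, 6000)),
                     strand = c("+", "+", "-", "-", "+"))
    exons$gene_id <- c("g1", "g1", "g2", "g2", "g3")
    utr5 <- GRanges(c("chrA", "chrA", "chrB"),
                    IRanges(c(5001, 13901, 4001), c(5100, 14000, 4080)),
                    strand = c("+", "-", "+"))
    utr5$gene_id <- c("g1", "g2", "g3")
    utr3 <- GRanges(c("chrA", "chrA", "chrB"),
                    IRanges(c(6851, 12001, 5851), c(7000, 12150, 6000)),
                    strand = c("+", "-", "+"))
    utr3$gene_id <- c("g1", "g2", "g3")
    makeGenomeAnnotation(c(chrA = 20000L, chrB = 10000L),
                         genes = genes, exons = exons,
                         utr5 = utr5, utr3 = utr3)
}

## All-pairs quadratic overlap oracle (independent of findOverlaps).
bruteIntersect <- function(a, b, minOverlap = 1) {
    out <- list()
    for (i in seq_along(a)) for (j in seq_along(b)) {
        if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j])
            next
        ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1
        if (ov >= minOverlap)
            out[[length(out) + 1]] <- c(i, j)
    }
    if (!length(out)) return(data.frame(a = integer(0), b = integer(0)))
    m <- do.call(rbind, out)
    data.frame(a = m[, 1], b = m[, 2])
}

## Per-base bitmap coverage oracle for merge/genome-fraction checks.
bitmapCoverage <- function(gr, chromSizes) {
    total <- 0L
    for (ch in names(chromSizes)) {
        v <- logical(chromSizes[[ch]])
        sel <- as.character(seqnames(gr)) == ch
        for (i in which(sel))
            v[start(gr)[i]:end(gr)[i]] <- TRUE
        total <- total + sum(v)
    }
    total
}

## Random sorted interval set on a small genome.
randomIntervals <- function(n, chromSizes, maxLen = 200) {
    ch <- sample(names(chromSizes), n, replace = TRUE)
    len <- sample.int(maxLen, n, replace = TRUE)
    s <- vapply(seq_len(n), function(i)
        sample.int(chromSizes[[ch[i]]] - len[i], 1), 1L)
    gr <- GRanges(ch, IRanges(s, s + len - 1L))
    gr[order(as.character(seqnames(gr)), start(gr))]
}

## Direct-summation hypergeometric tail oracle using exact choose().
hyperTailOracle <- function(k, K, N, n) {
    i <- k:min(n, K)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## Exhaustive-enumeration two-sided rank-sum oracle.
exactRankSumOracle <- function(x, y) {
    m <- length(x); nn <- length(y)
    pool <- c(x, y)
    combos <- utils::combn(m + nn, m)
    r <- rank(pool)
    uObs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    us <- apply(combos, 2, function(idx)
        sum(r[idx]) - m * (m + 1) / 2)
    pLo <- mean(us <= uObs)
    pHi <- mean(us >= uObs)
    min(1, 2 * min(pLo, pHi))
}

## One small default-condition dataset shared across test files (built
## lazily, reused thereafter).
.simCache <- new.env(parent = emptyenv())
defaultSim <- function() {
    if (is.null(.simCache$sim))
        .simCache$sim <- simulateDataset(simConfig(seed = 11))
    .simCache$sim
}
defaultAnalysis <- function() {
    if (is.null(.simCache$an))
        .simCache$an <- analyzeSimulation(defaultSim())
    .simCache$an
}
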