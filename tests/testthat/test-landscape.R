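test_that("replicate consolidation keeps only reciprocally supported peaks", {
    r1 <- GRanges("chr1", IRanges(1, 10)); r1$peak_id <- "a"
    r2 <- GRanges("chr1", IRanges(6, 15)); r2$peak_id <- "b"
    s <- consolidateReplicates(r1, r2, stage = "BBCH_11")
    expect_equal(length(acrPeaks(s)), 1L)
    expect_equal(c(start(acrPeaks(s)), end(acrPeaks(s))), c(1L, 15L))
    ## disjoint replicates -> empty set with warning
    r2 <- GRanges("chr1", IRanges(21, 30)); r2$peak_id <- "b"
    expect_warning(s <- consolidateReplicates(r1, r2), "reciprocal")
    expect_equal(length(acrPeaks(s)), 0L)
    expect_warning(consolidateReplicates(GRanges(), r2), "empty")
})

test_that("consolidation sums constituent counts per sample", {
    r1 <- GRanges("chr1", IRanges(c(1, 100), c(10, 120)))
    r1$peak_id <- c("a", "b")
    r2 <- GRanges("chr1", IRanges(c(6, 105), c(15, 125)))
    r2$peak_id <- c("c", "d")
    counts <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), nrow = 4,
                     dimnames = list(c("a", "b", "c", "d"), c("s1", "s2")))
    s <- consolidateReplicates(r1, r2, counts = counts)
    got <- mcols(acrPeaks(s))$counts
    expect_equal(unname(got[1, ]), c(1 + 3, 10 + 30))
    expect_equal(unname(got[2, ]), c(2 + 4, 20 + 40))
})

test_that("specificity classes partition the merged union", {
    mk <- function(starts, stage) {
        gr <- GRanges("chr1", IRanges(starts, starts + 9))
        gr$peak_id <- paste0(stage, seq_along(starts))
        new("StageACRSet", stage = stage, peaks = gr, source = "x")
    }
    stages <- acrStages()
    ## identical sets -> all common
    sets <- lapply(stages, function(st) mk(c(1, 100, 200), st))
    p <- classifySpecificity(sets)
    expect_equal(length(commonACRs(p)), 3L)
    expect_equal(sum(vapply(specificACRs(p), length, 1L)), 0L)
    ## disjoint sets -> all specific
    sets <- list(mk(1, stages[1]), mk(100, stages[2]), mk(200, stages[3]))
    p <- classifySpecificity(sets)
    expect_equal(length(commonACRs(p)), 0L)
    expect_equal(vapply(specificACRs(p), length, 1L),
                 setNames(rep(1L, 3), stages))
    ## two-stage peaks are partial, not specific
    sets <- list(mk(c(1, 100), stages[1]), mk(c(1, 300), stages[2]),
                 mk(500, stages[3]))
    p <- classifySpecificity(sets)
    expect_equal(length(partialACRs(p)), 1L)
    expect_equal(length(commonACRs(p)) + length(partialACRs(p)) +
                     sum(vapply(specificACRs(p), length, 1L)),
                 p@unionSize)
})

test_that("partition property holds on random stage sets", {
    set.seed(30)
    stages <- acrStages()
    cs <- c(chr1 = 50000L)
    sets <- lapply(stages, function(st) {
        gr <- mergeIntervals(randomIntervals(80, cs, maxLen = 150))
        gr$peak_id <- paste0(st, seq_along(gr))
        new("StageACRSet", stage = st, peaks = gr, source = "x")
    })
    p <- classifySpecificity(sets)
    u <- reduce(c(granges(acrPeaks(sets[[1]])), granges(acrPeaks(sets[[2]])),
                  granges(acrPeaks(sets[[3]]))))
    expect_equal(p@unionSize, length(u))
    expect_equal(length(commonACRs(p)) + length(partialACRs(p)) +
                     sum(vapply(specificACRs(p), length, 1L)), length(u))
})

test_that("self-sampling hook gives fold 1 for every observed category", {
    ann <- toyAnnotation()
    peaks <- GRanges("chrA", IRanges(c(3500, 5400, 8000),
                                     c(3700, 5600, 8300)))
    res <- permutationEnrichment(
        peaks, ann, nPermutations = 3,
        sampler = function(lens, cs) peaks)
    nz <- res$observed > 0
    expect_true(all(abs(res$fold[nz] - 1) < 1e-12))
})

test_that("fold enrichment matches the closed form on a promoter-only toy", {
    ## one gene on a 10 kb chromosome: the 2 kb promoter is 20% of the
    ## genome, so uniformly placed points land there w.p. ~0.2 and
    ## promoter-concentrated peaks show fold ~ 1 / 0.2 = 5
    g <- GRanges("c", IRanges(5001, 8000), strand = "+")
    g$gene_id <- "g"
    ann <- makeGenomeAnnotation(c(c = 10000L), genes = g)
    peaks <- GRanges("c", IRanges(seq(3100, 4900, by = 200),
                                  seq(3140, 4940, by = 200)))
    res <- permutationEnrichment(peaks, ann, nPermutations = 2000,
                                 seed = 99)
    fold <- res$fold[res$category == "promoter"]
    expect_lt(abs(fold - 5) / 5, 0.05)
    expect_lt(res$p_enrich[res$category == "promoter"], 0.001)
})

test_that("permutation p-values use the +1 correction and never reach 0", {
    ann <- toyAnnotation()
    peaks <- GRanges("chrA", IRanges(3500, 3700))
    res <- permutationEnrichment(peaks, ann, nPermutations = 50, seed = 1)
    expect_true(all(res$p_enrich >= 1 / 51))
    expect_true(all(res$p_deplete >= 1 / 51))
})

test_that("length matching holds in every permutation", {
    ann <- toyAnnotation()
    set.seed(4)
    peaks <- randomIntervals(20, chromSizes(ann))
    seen <- list()
    res <- permutationEnrichment(
        peaks, ann, nPermutations = 5,
        sampler = function(lens, cs) {
            seen[[length(seen) + 1]] <<- lens
            expect_equal(sort(lens), sort(width(peaks)))
            GRanges("chrA", IRanges(seq_along(lens) * 100,
                                    width = lens))
        })
    expect_equal(length(seen), 5L)
})

test_that("normalized chromatin length follows the printed formula", {
    ## 50 peaks total, a 10 bp chromosome in a 100 bp genome -> 50*10/100
    cs <- c(a = 10L, b = 90L)
    acrs <- GRanges(rep(c("a", "b"), c(5, 45)), IRanges(1, 2))
    cc <- chromosomeCorrelation(acrs, cs)
    expect_equal(cc$table$normalized_length[cc$table$chrom == "a"], 5)
    expect_equal(cc$table$normalized_length[cc$table$chrom == "b"], 45)
})

test_that("perfectly proportional counts give r = r2 = 1", {
    cs <- c(a = 1000L, b = 2000L, c = 3000L)
    acrs <- GRanges(rep(c("a", "b", "c"), c(10, 20, 30)), IRanges(1, 5))
    cc <- chromosomeCorrelation(acrs, cs)
    expect_equal(cc$r, 1)
    expect_equal(cc$r2, 1)
    expect_error(chromosomeCorrelation(acrs, cs[1]), "fewer than 2")
})
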