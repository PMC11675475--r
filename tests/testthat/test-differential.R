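test_that("median-of-ratios size factors recover planted scalings", {
    set.seed(10)
    base <- rpois(300, 200) + 1
    cnt <- cbind(s1 = base, s2 = base)
    expect_equal(unname(medianRatioSizeFactors(cnt)), c(1, 1))
    ## sample B exactly 2x sample A: factors (1/sqrt(2), sqrt(2))
    cnt <- cbind(a = base, b = 2L * base)
    sf <- medianRatioSizeFactors(cnt)
    expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
    ## fallback when no all-positive feature
    cnt <- cbind(a = c(0L, 5L), b = c(5L, 0L))
    expect_warning(medianRatioSizeFactors(cnt), "library-size")
})

test_that("planted library-size ratios are estimated within 5%", {
    libs <- c(1, 2, 0.5, 1.5) * 1e6
    sim <- simulateCountMatrix(1500, nPerGroup = 2, dispersion = 0.05,
                               sizeFactors = libs / mean(libs), seed = 21)
    sf <- medianRatioSizeFactors(sim$counts)
    planted <- libs / mean(libs)
    planted <- planted / exp(mean(log(planted)))
    expect_true(all(abs(sf / planted - 1) < 0.05))
})

test_that("identical groups give zero fold change and p near 1", {
    cnt <- matrix(rep(c(10L, 200L, 35L), each = 4), nrow = 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
    res <- nbTest(cnt, 1:2, 3:4, sizeFactors = rep(1, 4))
    expect_equal(res$log2fc, rep(0, 3))
    expect_true(all(res$p > 0.99))
    expect_false(any(res$significant))
})

test_that("the test is antisymmetric under group swap", {
    sim <- simulateCountMatrix(200, log2fc = 2, fracAffected = 0.3,
                               seed = 7)
    r1 <- nbTest(sim$counts, sim$groupA, sim$groupB,
                 sizeFactors = rep(1, 4))
    r2 <- nbTest(sim$counts, sim$groupB, sim$groupA,
                 sizeFactors = rep(1, 4))
    expect_equal(r1$log2fc, -r2$log2fc)
    expect_equal(r1$p, r2$p)
    ## and invariant to relabeling samples within a group
    r3 <- nbTest(sim$counts[, c(2, 1, 4, 3)], 1:2, 3:4,
                 sizeFactors = rep(1, 4))
    expect_equal(r1$p, r3$p)
})

test_that("all-zero features are excluded from testing and BH", {
    sim <- simulateCountMatrix(100, seed = 3)
    cnt <- sim$counts
    cnt[5, ] <- 0L
    res <- nbTest(cnt, 1:2, 3:4)
    expect_true(is.na(res$p[5]))
    expect_equal(res$direction[5], "ns")
    res2 <- nbTest(cnt[-5, ], 1:2, 3:4)
    expect_equal(res$padj[-5], res2$padj)
})

test_that("BH adjustment is monotone and padj >= p", {
    sim <- simulateCountMatrix(500, log2fc = 1.5, fracAffected = 0.2,
                               seed = 9)
    res <- nbTest(sim$counts, sim$groupA, sim$groupB)
    ok <- !is.na(res$p)
    expect_true(all(res$padj[ok] >= res$p[ok]))
    expect_equal(order(res$p[ok]), order(res$padj[ok], res$p[ok]))
})

test_that("null simulation keeps the discovery fraction at bay", {
    sim <- simulateCountMatrix(2000, nPerGroup = 2, dispersion = 0.05,
                               fracAffected = 0, seed = 13)
    res <- nbTest(sim$counts, sim$groupA, sim$groupB)
    expect_lte(mean(res$significant, na.rm = TRUE), 0.05)
})

test_that("planted strong effects are recovered with correct signs", {
    sim <- simulateCountMatrix(2000, baseMean = 500, dispersion = 0.05,
                               log2fc = 3, fracAffected = 0.1, seed = 17)
    res <- nbTest(sim$counts, sim$groupA, sim$groupB)
    hit <- res$significant[sim$affected]
    expect_gte(mean(hit), 0.9)
    signOK <- sign(res$log2fc[sim$affected & res$significant]) ==
        sim$sign[sim$affected & res$significant]
    expect_gte(mean(signOK), 0.95)
})

test_that("the Poisson limit agrees with an exact binomial oracle", {
    set.seed(23)
    n <- 300
    base <- runif(n, 50, 500)
    fc <- sample(c(1, 1.3, 1.6), n, TRUE)
    A <- matrix(rpois(n * 2, base), n)
    B <- matrix(rpois(n * 2, base * fc), n)
    cnt <- cbind(A, B)
    rownames(cnt) <- paste0("f", seq_len(n))
    res <- nbTest(cnt, 1:2, 3:4, sizeFactors = rep(1, 4),
                  dispersion = 1e-8)
    pb <- vapply(seq_len(n), function(i)
        stats::binom.test(sum(B[i, ]), sum(A[i, ]) + sum(B[i, ]))$p.value,
        1)
    keep <- pb > 1e-6 & pb < 0.9
    ratio <- res$p[keep] / pb[keep]
    expect_true(all(ratio < 2 & ratio > 0.5))
})

test_that("the NB test agrees with DESeq2 as an independent cross-check", {
    suppressMessages(suppressWarnings(library(DESeq2)))
    sim <- simulateCountMatrix(400, dispersion = 0.05, log2fc = 2,
                               fracAffected = 0.25, seed = 31)
    cond <- factor(rep(c("A", "B"), each = 2))
    dds <- DESeqDataSetFromMatrix(sim$counts, S4Vectors::DataFrame(cond),
                                  ~ cond)
    dds <- suppressMessages(DESeq(dds, quiet = TRUE))
    dres <- results(dds)
    res <- nbTest(sim$counts, sim$groupA, sim$groupB)
    ok <- !is.na(dres$padj) & !is.na(res$padj)
    ## effect sizes agree closely; significance calls mostly coincide
    expect_gt(cor(res$log2fc[ok], dres$log2FoldChange[ok]), 0.98)
    mine <- res$padj[ok] < 0.05 & abs(res$log2fc[ok]) > 1
    theirs <- dres$padj[ok] < 0.05 & abs(dres$log2FoldChange[ok]) > 1
    agree <- mean(mine == theirs)
    expect_gt(agree, 0.9)
})

test_that("the expressed-gene filter applies both stage rules", {
    fpkm <- rbind(
        gA = c(1.5, 2.0, 0.2, 0.3, 0.1, 0.4),  # stage 1 complete, 2 total
        gB = c(0.5, 0.2, 0.3, 0.1, 0.2, 0.3),  # nowhere
        gC = c(1.2, 0.8, 1.4, 1.1, 0.2, 0.1))  # stage 2 complete, 3 total
    stages <- sampleStages()
    expect_setequal(filterExpressed(fpkm, stages), c("gA", "gC"))
    expect_equal(filterExpressed(fpkm, stages, "threeSamplesTotal"),
                 c("gC"))
    expect_equal(filterExpressed(fpkm * 0, stages), character(0))
})

test_that("DEG union collects per-comparison significant genes once", {
    sim <- simulateCountMatrix(300, log2fc = 3, fracAffected = 0.15,
                               seed = 41)
    cnt <- cbind(sim$counts, sim$counts[, 3:4])
    colnames(cnt) <- sampleNames()
    deg <- identifyDEGs(cnt, sampleStages())
    expect_equal(anyDuplicated(deg$union), 0L)
    union2 <- sort(unique(unlist(lapply(deg$results, function(r)
        r$feature[r$significant]))))
    expect_equal(deg$union, union2)
})

test_that("intensity-expression correlation summarizes planted signs", {
    stages <- acrStages()
    ## intensity equals expression -> r = 1 everywhere
    pk <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), stages))
    ex <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), stages))
    asg <- data.frame(gene_id = c("g1", "g2"), peak_id = c("p1", "p2"))
    cs <- intensityExpressionCorrelation(pk, ex, asg)
    expect_equal(cs$fraction_positive, 1)
    expect_equal(cs$median_r, 1)
    ## anti-correlated genes are all negative
    ex2 <- ex[, c(3, 2, 1)]; colnames(ex2) <- stages
    cs2 <- intensityExpressionCorrelation(pk, ex2, asg)
    expect_equal(cs2$fraction_positive, 0)
    ## zero-variance genes are excluded
    pk0 <- rbind(pk, p3 = c(5, 5, 5))
    ex0 <- rbind(ex, g3 = c(1, 2, 3))
    asg0 <- rbind(asg, data.frame(gene_id = "g3", peak_id = "p3"))
    expect_equal(intensityExpressionCorrelation(pk0, ex0, asg0)$n, 2)
})
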