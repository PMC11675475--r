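## fpkm matrix whose genes follow the 8 default archetypes with mild noise
archetypeFpkm <- function(perCluster = 20, noiseSd = 0.1, seed = 5,
                          baseline = 4) {
    set.seed(seed)
    arch <- defaultArchetypes()
    genes <- paste0("g", seq_len(8 * perCluster))
    truth <- rep(seq_len(8), each = perCluster)
    stages <- sampleStages()
    mu <- arch[truth, sub("_R[0-9]+$", "", stages)] + baseline
    fpkm <- 2^(mu + rnorm(length(mu), 0, noiseSd))
    dimnames(fpkm) <- list(genes, sampleNames())
    list(fpkm = fpkm, truth = setNames(truth, genes))
}

test_that("planted archetype partitions are recovered almost perfectly", {
    ax <- archetypeFpkm()
    cl <- clusterDEGs(ax$fpkm, sampleStages(), names(ax$truth), k = 8,
                      seed = 1, archetypes = defaultArchetypes())
    ari <- mclust::adjustedRandIndex(ax$truth, cl$assignment[names(ax$truth)])
    expect_gte(ari, 0.9)
    ## archetype relabeling maps every planted cluster onto its own label
    tab <- table(ax$truth, cl$assignment[names(ax$truth)])
    expect_gte(sum(diag(tab)) / sum(tab), 0.95)
})

test_that("clustering is deterministic and duplicates share labels", {
    ax <- archetypeFpkm(perCluster = 6)
    fpkm <- rbind(ax$fpkm, dup1 = ax$fpkm[1, ], dup2 = ax$fpkm[1, ])
    genes <- rownames(fpkm)
    c1 <- clusterDEGs(fpkm, sampleStages(), genes, seed = 3)
    c2 <- clusterDEGs(fpkm, sampleStages(), genes, seed = 3)
    expect_identical(c1$assignment, c2$assignment)
    expect_equal(length(unique(c1$assignment[c("g1", "dup1", "dup2")])), 1L)
})

test_that("degenerate k = 1 puts every gene in one cluster", {
    ax <- archetypeFpkm(perCluster = 3)
    cl <- clusterDEGs(ax$fpkm, sampleStages(), names(ax$truth), k = 1,
                      seed = 1)
    expect_equal(unname(unique(cl$assignment)), 1L)
    expect_error(clusterDEGs(ax$fpkm[1:4, ], sampleStages(),
                             rownames(ax$fpkm)[1:4], k = 8, seed = 1),
                 "fewer genes")
})

test_that("cluster overlap Fisher matches the hypergeometric oracle", {
    ## 2x2 with k=3, n=5, K=4, N=20 against direct summation
    universe <- paste0("u", 1:20)
    clusters <- setNames(rep(2L, 20), universe)
    clusters[1:4] <- 1L                            # cluster 1 has K = 4
    set <- c("u1", "u2", "u3", "u10", "u11")       # n = 5, overlap k = 3
    res <- clusterOverlapFisher(list(S = set), clusters, universe)
    want <- hyperTailOracle(3, 4, 20, 5)
    expect_equal(res$p[res$cluster == 1], want, tolerance = 1e-12)
    expect_equal(res$proportion[res$cluster == 1], 3 / 5)
    ## a set identical to a cluster: proportion 1, smallest p there
    clusters2 <- setNames(c(rep(1L, 10), rep(2L, 90)),
                          paste0("v", 1:100))
    res2 <- clusterOverlapFisher(list(S = paste0("v", 1:10)), clusters2,
                                 names(clusters2))
    expect_equal(res2$proportion[res2$cluster == 1], 1)
    expect_lt(res2$p[res2$cluster == 1], res2$p[res2$cluster == 2])
    ## empty set after universe intersection
    res3 <- clusterOverlapFisher(list(S = "absent"), clusters2,
                                 names(clusters2))
    expect_true(all(res3$p == 1))
    expect_true(all(res3$proportion == 0))
})

test_that("one-sided Fisher equals direct summation on exhaustive tables", {
    for (N in c(8, 15, 26)) {
        for (n in 1:(N - 1)) for (K in 1:(N - 1)) {
            kmin <- max(0, n + K - N)
            for (k in kmin:min(n, K)) {
                mine <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
                expect_equal(mine, hyperTailOracle(k, K, N, n),
                             tolerance = 1e-9)
            }
        }
    }
})

test_that("DPI/DEG integration fills quadrants and reports conflicts", {
    mkRes <- function(feat, lfc, sig) data.frame(
        feature = feat, baseMeanA = 1, baseMeanB = 1, log2fc = lfc,
        p = 0.001, padj = ifelse(sig, 0.001, 0.9), significant = sig,
        direction = ifelse(sig, ifelse(lfc > 0, "up", "down"), "ns"))
    dpi <- list(cmp = mkRes(c("p1", "p2", "p3", "p4"),
                            c(2, -2, 2, -2), c(TRUE, TRUE, TRUE, TRUE)))
    deg <- list(cmp = mkRes(c("g1", "g2", "g3", "g4"),
                            c(2, -2, -2, 2), rep(TRUE, 4)))
    asg <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      peak_id = c("p1", "p2", "p3", "p4"))
    out <- integrateDPIDEG(dpi, asg, deg)$cmp
    expect_equal(unname(out$quadrants),
                 c(1L, 1L, 1L, 1L))
    ## conflicting promoter signs exclude the gene
    asg2 <- rbind(asg, data.frame(gene_id = "g1", peak_id = "p2"))
    out2 <- integrateDPIDEG(dpi, asg2, deg)$cmp
    expect_true("g1" %in% out2$conflicting)
    expect_equal(sum(out2$quadrants), 3L)
    ## empty DPI -> all quadrants zero
    dpi0 <- list(cmp = mkRes("p1", 2, FALSE))
    expect_equal(sum(integrateDPIDEG(dpi0, asg, deg)$cmp$quadrants), 0L)
    expect_error(integrateDPIDEG(dpi, asg, list(other = deg$cmp)),
                 "comparison labels")
})

test_that("set enrichment follows the hypergeometric tail", {
    universe <- paste0("g", 1:20)
    target <- paste0("g", 1:5)
    termMap <- list(T1 = c(paste0("g", c(1, 2, 3, 10))),   # k=3,K=4
                    T2 = paste0("g", 11:14),               # k=0
                    Tempty = character(0))
    res <- setEnrichment(target, universe, termMap)
    expect_equal(nrow(res), 2L)                    # empty term skipped
    expect_equal(res$p[res$term == "T1"], hyperTailOracle(3, 4, 20, 5),
                 tolerance = 1e-12)
    expect_true(res$significant[res$term == "T1"])
    expect_error(setEnrichment(c(target, "absent"), universe, termMap),
                 "subset")
})

test_that("random targets are significant at roughly the alpha rate", {
    set.seed(77)
    universe <- paste0("g", 1:200)
    termMap <- lapply(1:40, function(i) sample(universe, 25))
    names(termMap) <- paste0("T", 1:40)
    hits <- 0; total <- 0
    for (rep in 1:25) {
        target <- sample(universe, 30)
        res <- setEnrichment(target, universe, termMap, alpha = 0.05)
        hits <- hits + sum(res$significant)
        total <- total + nrow(res)
    }
    expect_lt(hits / total, 0.1)    # one-sided test at alpha = 0.05
})

test_that("motif scanning finds forward and reverse-complement hits", {
    seqs <- Biostrings::DNAStringSet(c(a = "TTACGTTT", b = "TTTTTTTT",
                                       c = "AAAACGTA"))
    expect_equal(unname(motifHits("ACGT", seqs)), c(TRUE, FALSE, TRUE))
    ## reverse-complement-only hit: motif AAGG, sequence holds CCTT
    seqs2 <- Biostrings::DNAStringSet(c("GGCCTTGG"))
    expect_true(motifHits("AAGG", seqs2))
    ## IUPAC degeneracy: R = A or G
    seqs3 <- Biostrings::DNAStringSet(c("TAAGGT", "TAGGGT", "TACGGT"))
    hits <- motifHits("ARGG", seqs3)
    expect_equal(unname(hits), c(TRUE, TRUE, FALSE))
})

test_that("planted motif abundance yields a strong Fisher signal", {
    set.seed(55)
    rnd <- function(n, len) vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
    target <- rnd(50, 60)
    plant <- sample(50, 40)
    target[plant] <- vapply(target[plant], function(s) {
        at <- sample(1, 1) + 10
        paste0(substr(s, 1, at - 1), "TGACCA", substr(s, at + 6, 60))
    }, "")
    bg <- rnd(200, 60)
    res <- motifEnrichment(target, bg, c("TGACCA"))
    expect_lt(res$p, 0.01)
    expect_true(res$significant)
    expect_gte(res$target_hits, 40)
    ## overlong motifs are skipped with a warning
    expect_warning(res2 <- motifEnrichment(target, bg,
                                           c(strrep("ACGT", 40))),
                   "skipped")
    expect_equal(nrow(res2), 0L)
})
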