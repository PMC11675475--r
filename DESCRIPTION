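Package: acrdyn
Title: Chromatin Accessibility Dynamics and Expression Coupling Across Developmental Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative ATAC-seq/RNA-seq analysis toolkit for multi-stage
    chromatin accessibility studies. Builds representative accessible chromatin
    region (ACR) sets from replicated peak calls, classifies ACRs into genomic
    feature categories with a fixed precedence, computes permutation-null fold
    enrichment of ACRs over feature categories, tests differential peak
    intensity and differential gene expression with a self-contained
    negative-binomial Wald test, links promoter ACR presence, multiplicity,
    length and intensity to gene expression, clusters differentially expressed
    genes into stage-pattern archetypes, and integrates accessibility and
    expression changes into concordant and discordant gene sets. A fully
    seeded synthetic-data generator plants known ground truth (stage-specific
    peaks, differential intensities, expression archetypes, discordant genes,
    promoter motifs) so that every analysis stage can be validated by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
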