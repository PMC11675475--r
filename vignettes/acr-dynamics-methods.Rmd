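---
title: "Methods: chromatin accessibility dynamics and expression coupling"
author: "acrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin accessibility dynamics and expression coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`acrdyn` implements an integrative analysis of accessible chromatin
regions (ACRs — ATAC-seq peaks) and gene expression across three
developmental stages with two biological replicates each. The pipeline
takes peak calls, per-peak Tn5 count matrices, fragment files and
gene-level FPKM/count tables as inputs; peak calling, read trimming and
alignment are upstream of this package. A fully seeded synthetic-data
generator plants known ground truth in every layer so that each analysis
stage can be validated by recovery rather than by unavailable raw data.

# The analysis model

## Representative stage ACR sets and specificity

Each stage's representative ACR set keeps only peaks supported by both
replicates (>= 1 bp overlap, the common interval-tool default, since no
fraction threshold is specified for this design) and merges supported
peaks into union intervals (`consolidateReplicates()`). Across stages,
the merged union of all consolidated sets is partitioned by support:
regions supported by exactly one stage are stage-specific, by two stages
partial, by all three common (`classifySpecificity()`). The trichotomy
makes the classes a true partition of the union, which is asserted by a
validity method.

## Feature categories and the permutation null

Every genomic position belongs to exactly one feature category under the
precedence promoter > 5' UTR > 3' UTR > exon > intron > intergenic. The
promoter is the 2 kb immediately upstream of the TSS, strand-oriented,
TSS-exclusive, clipped at chromosome edges. A peak is classified by its
summit, or by its midpoint when no summit is recorded — a single-point
rule that keeps classification total and unambiguous for peaks spanning
several features (whether a spanning peak should count in multiple
categories is genuinely open; the single-point rule is our resolution
and is configurable upstream by supplying summits).

Fold enrichment per category compares the observed category counts with
the mean over `nPermutations` random region sets (default 5000). Each
random set matches the observed set in size and length multiset
(length-matched by default; a fixed-width mode is available because a
fixed-width null is equally defensible when region lengths are
homogeneous); each region lands on a chromosome drawn with probability
proportional to chromosome length and a start uniform such that the
region fits. Random draws do not mask observed ACR loci — with ACRs
covering a few percent of the genome the bias is second-order, and
masking would complicate the null's closed form. Empirical one-sided
p-values use the +1 correction so p is never exactly 0 and never smaller
than 1/(n+1).

## Chromosome-level density

The normalized chromatin length of chromosome *c* is
`total peak count * length(c) / total genome length`; the Pearson r (and
r²) between these normalized lengths and the per-chromosome peak counts
summarizes whether ACR density scales with chromosome length.

## Differential peak intensity and differential expression

Both DPI (peak counts) and DEG (exon counts) use the same self-contained
negative-binomial Wald test (`nbTest()`):

* **Normalization** — median-of-ratios size factors computed on features
  with all-positive counts, rescaled to geometric mean 1, with a
  library-size fallback when no such feature exists.
* **Dispersion** — per-feature method-of-moments estimate from the
  pooled within-group variance, shrunk toward a log-linear
  mean-dispersion trend by geometric interpolation with weight 0.5, and
  floored at 1e-8. With two replicates per group the per-feature
  estimate is noisy; the trend supplies stability, and features whose
  moment estimate is non-positive take the trend value directly. A known
  dispersion can be supplied to bypass estimation (the Poisson limit is
  dispersion -> 0, where the test agrees with an exact binomial oracle
  on moderate p-values).
* **Test** — Wald statistic on log2(meanB/meanA) with a delta-method
  standard error `sqrt((1/muA + alpha)/nA + (1/muB + alpha)/nB)/ln 2`; a
  pseudocount of 0.5 enters the fold change only when a group mean is 0.
* **Multiplicity** — Benjamini-Hochberg across tested features;
  all-zero features are excluded from testing and from the BH
  denominator.
* **Significance** — adjusted p < 0.05 and |log2 fold change| > 1, the
  shared criterion for DPI and DEG calls.

Exact numerical parity with any particular published estimator is a
non-goal; the test is calibrated (null discovery fraction <= nominal)
and powered (recall >= 0.9 at |log2FC| = 3, base mean 500, dispersion
0.05, 2 vs 2), which the test suite asserts.

The expressed-gene filter nominally requires FPKM > 1 in at least three
samples of a single stage; with two replicates per stage that is
unsatisfiable, so the default rule requires FPKM > 1 in **all
replicates of at least one stage**, and a "three samples overall"
variant is selectable.

## Promoter linkage and expression coupling

An ACR is assigned to a gene when its classification position falls in
the gene's promoter window; an ACR inside overlapping windows goes to
the nearest TSS, with exact ties assigned to all tied genes and flagged.
Downstream summaries: expression by promoter-ACR count (groups 0/1/2/3+,
adjacent groups compared by a two-sided rank-sum test), length tertiles
of single-ACR genes (stable sort by length descending then gene id;
tie-runs straddling a group boundary are interleaved round-robin across
the straddled groups so equal-length ACRs are balanced), and a 6-bin
association table (FPKM = 0 plus expressed-gene quintiles, classes
promoter-only / body-only / both / none, proportions summing to 1 per
bin). The caption-level "signed-rank" wording for independent gene
groups is interpreted as the rank-sum (Mann-Whitney) test, since
signed-rank requires pairing that does not exist between groups; exact
enumeration is used when the combined sample size is at most 12 and no
ties are present, and the normal approximation with tie and continuity
correction otherwise.

## Clustering and integration

DEGs are clustered on z-scored per-gene stage means of log2(FPKM+1) with
seeded multi-start k-means (k = 8, 10 starts, best inertia). Because the
method behind the published eight clusters is unstated, k-means on
z-scored stage means is our choice: it is simple, deterministic under a
seed, and its centroids map onto stage-pattern archetypes. When
archetype patterns are supplied, one additional k-means run initialized
at the z-scored archetypes competes by total within-cluster sum of
squares; this guards against the known k-means failure mode of merging
two adjacent patterns while splitting a dense one, and the winning
solution is still chosen purely by inertia. Clusters are then relabeled
by greedy nearest-archetype matching so labels are comparable across
runs.

Set-level analyses are generic: cluster overlap uses one-sided Fisher
tests over the DEG union as universe (the natural universe when overlap
percentages are read as shares of DEG clusters; configurable), term
enrichment is a one-sided hypergeometric test with a raw-p threshold of
0.05 (BH column reported), and motif enrichment scans IUPAC consensus
strings (forward and reverse complement, exact match by default) and
compares target versus background hit counts with a one-sided Fisher
test at p < 0.01. A position-weight-matrix scanner is a documented
extension point; consensus scanning suffices to validate enrichment
logic against planted motifs.

Integration places every gene with at least one significant promoter
DPI peak and a significant DEG call in the same comparison into one of
four quadrants by the two signs; genes whose significant promoter peaks
disagree in sign are excluded and reported. Concordant quadrants
(up/up, down/down) capture accessibility-driven expression; discordant
quadrants are the repressor-binding signature.

The per-gene intensity-expression correlation summarizes, across the
three stages, the Pearson r between the summed normalized intensity of
a gene's significant promoter DPI peaks and its stage-mean FPKM. The
universe is restricted to genes with a significant promoter DPI because
the quantity describes how detected accessibility *changes* track
expression; for peaks with no detected change the correlation would be
noise around zero and the summary would measure nothing. The wider
universe (any tested promoter peak) remains available via
`onlySignificant = FALSE`-style filtering of the assignment table.

# The synthetic-data generator

`simulateDataset()` draws every artifact from a single master seed with
a documented splitting scheme: sub-generator *k* (genome, ACRs, counts,
expression, fragments, sequence, clustering) seeds its stream with
`seed * 1000 + k`, so artifacts are independently reproducible and the
whole dataset is byte-identical across runs and platforms.

Default study conditions (chosen once, to mirror the qualitative
structure of a three-stage leaf development design at desk scale):

* **Genome** — 2 chromosomes (950 kb + 700 kb), 300 genes allocated
  proportionally to chromosome length, each with a 2 kb upstream flank,
  2-3 exons, 5'/3' UTRs, ~50% minus strand, intergenic gaps of
  1.0-1.6 kb. The genome is gene-dense compared with a real plant
  genome; that compresses intergenic space but leaves every analysis
  statistic well-defined.
* **ACR landscape** — 450 shared peaks present at all stages and
  (120, 40, 40) stage-specific peaks, echoing the strong first-stage
  skew of specific accessibility in leaf development. Placement
  probabilities promoter .30 / 5'UTR .05 / exon .05 / intron .30 /
  3'UTR .05 / intergenic .25; per-category lengths with the 3' UTR
  longest (800 bp) and intergenic shortest (250 bp). Replicate files
  jitter each peak edge by at most 20 bp, so the >= 1 bp overlap
  criterion always links true replicate pairs.
* **Counts** — NB with dispersion 0.05 around log-normal base means
  (median ~300); 30% of shared peaks carry a +-2 log2 intensity effect
  at one designated stage. Stage-specific peaks keep a 3% residual
  background mean at absent stages.
* **Expression** — log2 FPKM = baseline (N(3.5, 1)) + 1.5 x
  accessibility score + archetype offset + N(0, 0.4) per sample, where
  the score sums `(length/500) * log2((normalized mean count + 5)/100)`
  over the gene's promoter peaks present at the stage. The log-scale
  form transmits a planted +-2 intensity effect symmetrically to
  expression. Raw exon counts are NB-sampled from the target FPKM
  (count = FPKM x gene length x library size / 1e9) and FPKM is
  recomputed from the sampled counts, so both surfaces are mutually
  consistent. The per-sample noise of 0.4 log2 units reproduces
  replicate log-expression correlations of about 0.98.
* **Archetypes** — 200 genes split over 8 stage patterns whose z-scored
  forms are distinct directions on the circle of centered 3-vectors
  (amplitude 3 log2 units). The three "stage-up" directions (0°, 120°,
  240°) carry the single-stage archetypes (C1, C8, C7) because genes
  whose promoters gain a stage-specific peak drift toward exactly these
  directions; aligning archetypes with the drift keeps planted labels
  recoverable. Stage-specific promoter peaks preferentially target the
  matching archetype's genes (probability 0.8), and otherwise fall back
  to non-cluster genes without a shared promoter peak so planted
  signals never contradict each other.
* **Discordant genes** — 8 genes whose single promoter peak carries a
  DPI effect get a mean-preserving sign flip of the accessibility term
  (expression moves opposite to accessibility, at unchanged average
  level), emulating repressor binding to newly accessible promoters
  without modeling TF kinetics. Hosting peaks preferentially carry
  accessibility gains, the canonical repressor scenario. The generator
  tops up the DPI set with additional promoter peaks when uniform
  selection yields too few to host the discordant genes plus a
  concordant majority.
* **Fragments** — 150,000 per sample; midpoints are a 30% uniform
  background plus peak-centered normals (sd = length/4) weighted by the
  peak's realized count, with promoter peaks up-weighted 2x, producing
  the TSS pile-up that the metaprofile stratifies by expression decile.
* **Sequence** — uniform random nucleotides with the GCC-box-like
  consensus AGCCGCC embedded in 80% of C1-gene promoter peaks and the
  ABRE-like ACGTGTC in C7-gene promoter peaks; placements are recorded
  in the truth set.

What the generator does **not** emulate: read-level artifacts
(duplicates, Tn5 sequence bias, mappability), organellar contamination,
GC-dependent coverage, isoform structure beyond one transcript per
gene, distal regulation beyond the 2 kb promoter, and a realistic
gene-sparse genome. Passing recovery tests therefore demonstrates that
the analysis logic is correct and calibrated under its stated
assumptions — not that those assumptions hold in any particular real
library.

# Numerical choices and degenerate inputs

* Interval algebra runs on 1-based closed coordinates (the GRanges
  convention); BED input/output converts at the boundary, GFF3 is
  native. Bookended intervals merge at `maxGap = 0`.
* Readers reject malformed lines with their line number; writers emit
  files their own readers re-parse identically.
* Empty peak sets, all-zero count rows, zero-variance vectors, groups
  with fewer than two members, and terms with no annotated genes are
  handled explicitly (warning, exclusion, or p = 1 as documented).
* FPKM ranking ties break by gene id; tertile tie-runs interleave
  round-robin; k-means ties are resolved by the seeded start and the
  inertia comparison. All pipelines are byte-reproducible for a fixed
  seed.

# Problem sizes

The shipped test suite and the acceptance script run the default
synthetic study (2 chromosomes, 1.65 Mb, 300 genes, ~650 peaks, 6
samples, 150k fragments each), 2000-permutation enrichment nulls,
2000-feature differential calibration/power simulations, exhaustive
2x2-table checks to N = 60, and 100-case rank-test enumeration suites —
sizes chosen so a complete validation runs on a laptop in minutes while
keeping every Monte-Carlo tolerance comfortably powered.

# Known limitations

* The NB dispersion trend is a single log-linear fit; with very few
  features (< 10 with positive moment estimates) it degrades to a
  constant.
* The permutation null does not model GC or mappability matching, and
  random regions may overlap observed ACRs.
* Consensus motif scanning has no mismatch-weighted scoring; motifs at
  IUPAC degeneracy beyond simple codes inflate background hit rates.
* The intensity-expression summary treats a gene's significant promoter
  peaks as one summed signal; genes with opposing peaks are reported
  but not decomposed.
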