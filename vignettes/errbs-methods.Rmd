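---
title: "Methods: differential CpG methylation analysis for enhanced RRBS"
author: "errbs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential CpG methylation analysis for enhanced RRBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errbs)
```

# The problem

Reduced representation bisulfite sequencing (RRBS) digests genomic DNA with
MspI (which cuts `C^CGG` regardless of CpG methylation), size-selects the
fragments, bisulfite-converts them and sequences the result. Because
unmethylated cytosines deaminate to uracil (read as T) while methylated
cytosines resist conversion, the C/T counts over a cytosine measure its
methylation level at base-pair resolution. MspI sites cluster in CpG
islands, so the classical 40–220 bp size window over-represents islands;
the enhanced protocol (ERRBS) selects 70–320 bp fragments instead, pulling
in shores, introns and distal intergenic CpGs.

`errbs` implements the computational arm of such a study: methylation-call
I/O, in-silico digestion, filtered strand-merged calling, island/shore and
gene-feature annotation, per-CpG differential methylation testing between a
test and a control group of samples, enrichment statistics around
ChIP-defined elements and repeats, and the coupling of promoter methylation
to gene expression. A synthetic methylome generator with recorded ground
truth makes every stage testable without patient data.

# Statistical model

## Per-CpG differential methylation

For one CpG and two groups, methylated and unmethylated read counts are
pooled within each group (summing across the group's samples). The test is
the likelihood-ratio test of the binomial logistic regression with group
membership as the only covariate against the intercept-only null. With a
single categorical covariate the maximum-likelihood fit is available in
closed form from the pooled counts, and the deviance difference equals the
G statistic on the pooled 2×2 table,

$$G \;=\; 2\sum_{\text{cells}} O \,\ln\!\frac{O}{E}, \qquad 0\ln 0 := 0,$$

referred to a chi-square distribution on one degree of freedom.
`logisticLrtTest()` implements this closed form (the test suite holds it to
`stats::glm` fits to 1e-8 and to the G formula over an exhaustive sweep of
small tables). The effect size is the *pooled percent difference*: percent
methylation per group from the pooled counts, test minus control.

A differentially methylated cytosine (DMC) requires both `q < 0.01` and an
absolute pooled difference of at least 25 percentage points (10 and 40 are
robustness cutoffs; DMC sets nest across them). Testing is restricted to
CpGs covered at ≥ 10× in *every* sample of both groups, after merging the
forward-strand C and reverse-strand G observations of each CpG dinucleotide
and discarding read bases below phred 20.

## SLIM q-values

P-values are adjusted with a sliding-linear-model estimate of the true-null
proportion π₀: the survival count N(λ) = #{p > λ} is, for λ beyond the
alternatives, approximately n·π₀·(1−λ). `adjustPvaluesSlim()` fits a
through-origin line to N(λ) against (1−λ) in sliding windows over
λ = 0.01…0.95 (step 0.01, window 10 points), takes the slope of the most
linear window (smallest relative residual error), and returns
q = π₀ · BH(p), clipped to 1. This keeps q monotone in p. Below 100
p-values the π₀ fit is unstable and the function falls back to plain
Benjamini–Hochberg, with a message.

## Exact tests

Peak-overlap and repeat-enrichment contrasts use a two-sided Fisher exact
test under the *minimum-likelihood* convention: the p-value is the sum of
hypergeometric point probabilities not exceeding the observed table's (with
the customary 1+1e-7 tolerance). This convention reproduces published
peak-overlap p-values exactly at printed precision. The reported odds ratio
is the plain `ad/bc`, with a flagged Haldane (+0.5) correction on zero
cells. Repeat enrichment odds ratios are computed from the overlap
fractions, `(f/(1−f))/(b/(1−b))`, against the covered-CpG background.
Wilcoxon rank-sum tests are enumerated exactly up to a combined n of 20
(no ties) and use the tie-corrected normal approximation otherwise.

# Annotation rules

* **Shores** are the 2 kb flanks of each CpG island, clipped so a shore
  never reaches into a neighbouring island, clipped at chromosome ends, and
  merged when they overlap. The result is disjoint from islands, internally
  disjoint, order-independent, and no shore exceeds 4 kb.
* **Genome partition**: promoter (TSS ± 1 kb) > exon > intron > intergenic.
  The precedence is a package decision — each CpG must get exactly one
  label, and promoter-centric analyses need promoter to win. Island context
  is island > shore > beyond-shore, independently of the gene partition.
* **TSS distance** is signed by gene orientation (negative = upstream);
  ties between equidistant TSSs go to the lexicographically smallest
  transcript id, a deterministic convention.
* **Promoter CpG classes** follow the windowed criteria of the standard
  HCP/ICP/LCP classification: 500 bp windows at 5 bp steps; HCP if any
  window reaches CpG obs/exp ≥ 0.75 *and* GC ≥ 55%; LCP if no window
  reaches obs/exp 0.48; ICP otherwise, with
  obs/exp = (#CpG · N)/(#C · #G). Thresholds are arguments.
* **Enhancers** (operational): H3K4me1 peaks not overlapping any H3K4me3
  peak of the same cell line, union-merged across lines. Peaks are extended
  500 bp per side before DMC overlap; a peak holding both a hyper- and a
  hypomethylated DMC counts in both direction rows (the published table
  convention is not stated; `anyDmcExclusive` reports the once-only count
  alongside).

Internally all coordinates are 1-based closed `GRanges`; BED input/output
is converted at the boundary, and the bismark-style coverage and
cytosine-report dialects are 1-based. In input files, counts are
authoritative over printed percentages (a derived column cannot outrank its
source); disagreement beyond 0.1 warns.

# The synthetic methylome generator

The generator emulates the study conditions the analysis assumes, and its
defaults *are* those conditions:

* **Genome**: 2 chromosomes × 2.5 Mb assembled from dinucleotide tokens so
  CpG and CCGG densities are controlled exactly (fillers can create no CG
  across token boundaries). 60 islands per chromosome (~800 bp, CpG density
  0.08 vs 0.010 background; MspI-dense), 80 genes (70% with island-anchored
  TSSs), repeats as interval annotation over ~12% of the genome.
* **Methylation**: bimodal baselines — islands 5%, background 85% — with a
  fixed per-site beta spread (precision 15) shared by all samples.
* **Sampling noise**: coverage per site is negative-binomial with mean 50
  (the assay's ~53× average), split evenly between strands; per-sample
  methylation is beta-distributed around the site mean (precision 300);
  counts are binomial per strand and merged. The two precisions were
  calibrated once so replicate–replicate Pearson correlation of percent
  methylation lands near the 0.92–0.96 range the assay reports (realised
  ~0.95–0.97 at the default scale), and not revisited. Bisulfite
  conversion failure (default 0.2%, i.e. a 99.8% conversion rate) adds
  spurious methylation; non-CpG cytosines expose it for QC.
* **Planted architectures**: subtype H receives 2,000 sites, 90%
  hypermethylated at promoter-island CpGs and 10% hypomethylated at
  background CpGs; subtype L receives 3,000 sites, 72% hypomethylated at
  shore/intron/distal background CpGs and 28% hypermethylated at distal
  (non-promoter) island CpGs — the low island baseline is the only place a
  +40 gain fits, mirroring the distal-island targeting of the
  hypomethylation-dominated subtype. A shared core of 500 sites (79%
  hyper) is planted in both. Effects are ±40 percentage points on the
  pooled scale, clamped to [0, 100]; direction fractions are exact by
  construction and recorded as ground truth.
* **Expression**: each gene has a fixed log2 baseline (mean 8, sd 1)
  shared across conditions; genes with planted promoter-island
  hypermethylation in a condition are shifted down by 2 log2 units
  (promoter methylation represses), plus per-condition noise (sd 0.25).

What the generator does *not* emulate: read-level sequences and alignment
artefacts, M-bias, SNPs, copy-number change, repeat-driven methylation
structure (repeats are uniform intervals, so repeat enrichment is exercised
on constructed layouts rather than emergent signal), and biological
covariance between neighbouring CpGs beyond island/background structure.
Passing tests therefore demonstrate correctness of the statistical
machinery and recoverability of planted effects under realistic noise — not
performance on the full complexity of patient methylomes.

# Numerical and design choices

* The type-I error of the count-level test is inflated by the biological
  (beta) dispersion the pooled binomial model ignores; at the calibrated
  dispersion the per-site fraction with p < 0.05 on null two-vs-two
  comparisons stays ≤ 0.08 (tested). This is a documented caveat of
  count-level testing, not corrected for, matching the method's design.
* Fragment size windows are inclusive on both ends; in-silico digestion
  cuts at `C^CGG` (offset 1) on forward-strand coordinates only — CCGG is
  its own reverse complement, so one strand suffices for CpG accounting. A
  CpG on a fragment edge belongs to the fragment containing the C.
  Terminal fragments are flagged not-enzyme-flanked; digestion keeps them,
  and `selectFragments(requireBothCuts = TRUE)` drops them.
* Expression percentile groups use the two-sided step function: high means
  P(X ≤ x) > 0.85, low means P(X < x) < 0.15. The strict one-sided rule
  cannot simultaneously make "top 15%" of 100 distinct values 15
  transcripts and classify a two-value table; the two-sided form does both
  and is symmetric. Fold-change is log2 of the ratio of group means (raw
  ratio available).
* Ward clustering uses `hclust(method = "ward.D")` on 1 − Pearson
  distances — the agglomeration the original R implementation of this
  analysis generation used — fixed for reproducibility. Region-level
  correlation averages percent methylation over regions with ≥ 3 covered
  CpGs first.
* Zero-coverage and ambiguous rows in input files are dropped with
  warnings; the conversion rate is estimated from non-CpG (CHG/CHH)
  cytosines, the standard surrogate when no spike-in is available.

# Problem sizes

The bundled tests run the full pipeline on the default-scale synthetic
cohort (two replicates per condition over ~56,000 CpGs, of which ~50,000+
shared sites survive the 10× everywhere filter) and exercise unit
behaviour on a miniature 500 kb genome. Exhaustive oracle sweeps cover all
pooled 2×2 tables with totals ≤ 50 (logistic LRT vs G formula) and all
2×2 tables with totals ≤ 60 (Fisher p vs first-principles hypergeometric
enumeration), plus 1,000 random island configurations for the shore
construction invariants. These sizes were chosen as the smallest at which
the cohort statistics (replicate correlation, DMC counts, clustering) are
stable.

# A worked sketch

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 1L)
sg <- generateGenome(cfg)
truth <- plantDifferentialArchitecture(sg)
tabs <- simulateCohort(truth, cfg)

res <- diffMethTest(tabs, sampleSet(c("subtypeH_1", "subtypeH_2"),
                                    c("NBM_1", "NBM_2")))
dmcs <- callDmcs(res, qvalueCutoff = 0.01, diffCutoff = 25)
table(dmcs$status)

univ <- sharedSites(tabs, 10)
cl <- sampleClustering(pctMethMatrix(tabs, univ))
plot(cl$hclust)
```

`runPipeline()` drives the same stages over plain-text artifacts
(FASTA/BED/refFlat/TSV) with a manifest, for file-based reproduction.

# Known limitations

Single-CpG testing only (no windowed DMR calling), no covariates or
overdispersion correction in the test, no duplicate/M-bias/SNP handling
upstream, and expression integration assumes pre-summarised per-transcript
values on a common scale. These mirror the scope of the analysis the
package implements.
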