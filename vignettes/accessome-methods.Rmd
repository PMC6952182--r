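---
title: "Methods: accessome construction and downstream chromatin-accessibility analysis"
author: "accessome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accessome construction and downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

This package implements the downstream analysis layer for bulk ATAC-seq
studies of developmental lineages: it consumes called peaks, fragment-count
matrices, gene models and differential-expression tables, and produces a
reference atlas of accessible regions (the *accessome*), genomic-feature
annotation with exact enrichment statistics, differential accessibility
across perturbation and time-course designs, named peak/gene sets by
thresholded set algebra, peak-level GSEA, PWM-based motif analysis, and
chromVAR-style motif accessibility deviation Z-scores. Read trimming,
alignment and peak calling are upstream and out of scope; the package
starts from peaks and counts.

The running example throughout is a cardiopharyngeal-lineage design: a
reporter-labelled embryonic lineage (here called B7.5, with a mesenchyme
outgroup) sampled at 6–20 hours post-fertilization under FGF-MAPK pathway
perturbations (dominant-negative FGF receptor, constitutively active Mek or
M-Ras) and a Foxf CRISPR loss-of-function, with matched controls. Nothing
in the code is specific to that system; the design vocabulary is just the
default the synthetic-data generator and the packaged model designs speak.

# The accessome

`mergeToAccessome()` concatenates per-sample peak sets, merges overlapping
*and book-ended* intervals (two peaks sharing a boundary become one,
matching `bedtools merge` defaults), and drops merged intervals of length
≤ 50 bp — strictly, so 51 bp is the shortest retained peak. The result is
an `Accessome`, a `GRanges` subclass whose validity object enforces the
atlas invariants: sorted, pairwise non-overlapping, unstranded, inside
chromosome bounds, with unique stable `peak_id`s assigned in sorted order
(`chrom:start-end` in BED coordinates plus a rank). All internal
coordinates are 1-based `GRanges`; BED and GFF3 conversion happens at the
I/O boundary via `rtracklayer`, so no hand-rolled off-by-one arithmetic
exists anywhere in the package.

Merging is deliberately unstranded: ATAC-seq accessibility has no strand.
Merge is idempotent and invariant to input order; genome coverage is the
exact ratio of summed peak lengths to summed chromosome lengths.

# Feature annotation

`buildFeatureMap()` derives strand-aware windows from gene models:

| feature | definition | default |
|---|---|---|
| TSS | ± `tssHalfwidth` around the 5'UTR start | 107 bp |
| promoter | `promoterLength` upstream of the TSS, split into proximal/distal halves | 1000 bp (2 × 500) |
| TTS | ± `ttsHalfwidth` around the 3'UTR end | 200 bp |
| intron | transcript span minus exons | — |

The TSS anchor is the start of the annotated 5'UTR rather than the
transcript start because in tunicates roughly half of protein-coding
transcripts are spliced-leader trans-spliced: the mature mRNA 5' end is
not the transcription start, and the annotated UTR start is the reliable
proxy. Transcripts without a 5'UTR fall back to the transcript start. The
107 bp half-width is taken as given (it summarizes the span of empirical
TSS clusters); deriving it from TSS-seq data is out of scope.

`classifyPeaks()` is multi-label — a peak carries every feature it overlaps
by ≥ 1 bp, and `intergenic` only when it overlaps none — because each
feature is tested independently. A single primary label per peak uses the
precedence TSS > promoter > 5UTR > exon > 3UTR > TTS > intron
(configurable) for distribution plots only.

Feature enrichment uses an exact two-tailed binomial test
(`binomialEnrichment()`) with the genome fraction covered by the feature as
the null probability: if promoters cover 10 % of the genome, 10 % of peaks
are expected to overlap them by chance. Two-sidedness is minimum-likelihood
summation — the p-value sums the probabilities of all outcomes no more
likely than the observed count — which is well defined for asymmetric
nulls, unlike tail doubling. The same engine drives the
intersection-independence test (below).

`associatePeaksToGenes()` links a peak to every gene whose transcript-union
span lies within 10 kb (gap counted in bases between the features; a peak
exactly 10,000 bp away is associated, 10,001 is not). Distances are signed
by gene orientation: negative upstream of the 5' end, 0 for overlap,
positive downstream. The union-span dialect (rather than per-TSS/TTS
anchors) is the recorded default because it is the superset of the
anchor-based reading and keeps one association dialect shared by every
module — "associated with" means the same thing in set algebra, GSEA
lifting and primed/de novo classification.

# Differential accessibility

The count model is the negative binomial with `Var = mu + alpha * mu^2`,
log link, and a log size-factor offset. Size factors are median-of-ratios
(per-sample median of count ratios to the row geometric mean over
all-positive peaks), falling back to library-size scaling when fewer than
100 peaks are all-positive — the standard normalization for count data
where most features do not change.

**Dispersion.** Per-peak dispersions are estimated by maximizing the
Cox–Reid adjusted profile likelihood within the factor cells of the full
design (the cell means profile out in closed form under the log link), then
summarized into a mean–dispersion trend by robust regression of log
dispersion on log mean; the trend value at each peak's mean is the working
dispersion. Using the within-design cells matters: a naive pooled variance
would read genuine condition effects as dispersion and destroy power.
Per-peak departures from the trend are *not* folded into the point estimate
— they are handled by the test itself.

**Test.** Each peak is fitted under the full and the nested reduced design
(IRLS via `stats::glm.fit` with the `MASS` NB family at the fixed working
dispersion), giving the likelihood-ratio statistic `2(l_full − l_reduced)`
with df equal to the design rank difference. The statistic is referred to
a quasi-likelihood F reference rather than a chi-square: the residual
deviance dispersion of the full fit is empirical-Bayes squeezed across
peaks (`limma::squeezeVar`) and `F = (LRT/df) / s2_post` is compared with
`F(df, df_residual + df_prior)`. The reason is small-sample honesty: with
the *true* dispersion the chi-square LRT is exactly calibrated, but with
dispersions estimated from a handful of replicates the plug-in chi-square
is anticonservative (we measured ~0.07–0.09 empirical type-I at nominal
0.05 with 4 vs 4 replicates, for every point estimator we tried), while
the QL-F construction absorbs the estimation uncertainty and restores the
nominal level (~0.045 measured under both constant and heterogeneous true
dispersion). This mirrors the standard quasi-likelihood practice for
small-replicate count GLMs. Log2 fold changes are raw MLE contrasts of the
full-model coefficients — no shrinkage — reported per named contrast; the
LRT tests the whole factor, so every contrast table from one design shares
its p-values. All-zero and non-converged peaks are NA and excluded from
the BH correction. No outlier filtering is applied.

Deliberately *not* implemented: the empirical-Bayes dispersion machinery
and fold-change moderation of the established RNA-seq packages. The module
is validated by simulation — type-I calibration within the exact 99 %
binomial envelope and recovery of planted effects — not by matching any
external implementation's numbers.

**Packaged designs.** `runDifferentialModel()` builds four designs:
condition differences among the 10 hpf perturbations versus a constant
null; perturbations versus controls across 15–20 hpf with a timepoint
covariate in both designs; the control time course versus a constant null;
and lineage (B7.5 versus mesenchyme) with a timepoint covariate. Contrast
`A_vs_B` always reports `log2(A) − log2(B)`; in the time model,
`t10_vs_t18 < 0` means less accessible at 10 than at 18 hpf.

`filterLibraries()` drops samples with fewer than 500,000 fragments
(strict: exactly 500,000 is kept) and errors, naming the group, if a
compared group is left with a single replicate. `rpkmMatrix()` and
`sampleCorrelation()` provide the Spearman reproducibility QC.

# Peak-set and gene-set algebra

All printed thresholds are strict inequalities exactly as typeset
(`|log2FC| > 0.5`, `FDR < 0.05`; a peak at exactly −0.5 is excluded). The
six accessibility sets are unions/differences of thresholded contrasts:
FGF-MAPK-opened and -closed at 10 hpf and at 18 hpf, plus *de novo*
(closed in control 10 versus 18 hpf, minus the FGF-opened set) and
*primed* (FGF-opened at 10 hpf, minus peaks closed in control 10 versus
18 hpf) — disjoint by construction. Expression gene sets follow the same
grammar (Foxf targets at log2FC < −0.75 and FDR < 0.05; the MAPK
activated/inhibited intersections at |log2FC| > 1; microarray-based 10 hpf
sets on unadjusted p). `thresholdSet()` exposes the grammar (union /
intersect / minus over sign-lfc-fdr rules, YAML-friendly) for user-defined
sets, and every set carries its defining rules as provenance.

Primed/de novo elements are classified cardiac- versus pharyngeal-muscle
(ASM)-accessible by the 18 hpf direction rules (strict signs; a fold
change of exactly 0 qualifies for neither), and elements whose
accessibility could reflect an earlier program are removed: ASM elements
associated with any cardiac or MAPK-inhibited gene are dropped, cardiac
elements associated with any ASM or MAPK-activated gene are dropped.

The intersection-independence test asks whether the overlap of k sets is
what independence predicts: the null probability is the product of the
sets' relative sizes, the observation is the intersection size out of the
universe, and the p-value is the same minimum-likelihood two-sided
binomial used for feature enrichment. A single set is always
null-consistent (p = 1).

# Peak-level GSEA

Gene sets are lifted to peak sets through the association map (a peak in
two member genes counts once), the accessome is ranked by the log2 fold
change of a chosen contrast, and the classic weighted Kolmogorov–Smirnov
running sum is walked: member peaks step up by `|stat|^w / sum`, others
step down by `1/(N−m)`; the enrichment score is the signed extremum (ties
break toward the positive side). The weight exponent defaults to `w = 1`
(the cited implementation's default); `w = 0` reproduces the plain
"running tally" reading and is supported — the exponent is recorded in the
output. The null distribution shuffles membership labels over the ranked
list (peak permutation, not phenotype permutation, matching the method's
description), NES divides the observed score by the mean |score| of
same-sign permutations (the standard sign-split convention; the source
description does not spell it out), and the permutation p-value carries
the +1 correction so it can never be zero. Sets with fewer than 5 member
peaks in the ranking are skipped. With a fixed seed the permutation
stream, and hence every number, is bit-reproducible; an O(m) evaluation
from member positions only makes 10,000 permutations cheap.

# Motif toolkit

**Scoring and thresholds.** A PWM is a strictly positive per-position
probability matrix (pseudocount 0.8 split by background — a common
default, recorded in the object; the source does not state one). Match
scores are log2 odds against background nucleotide frequencies computed
from the full accessome sequence set. Scores are discretized on a lattice
of 1e-3 bits (configurable); `pwmThreshold()` computes the exact
distribution of the lattice score under the background by dynamic
programming (position-wise convolution) and returns the smallest
*achievable* score whose upper tail is ≤ the match-probability cutoff
(default p < 5e-5). The scanner scores windows on the same lattice, so the
threshold and the scan are exactly consistent and the lattice granularity
is the single, documented source of approximation. A degenerate motif
whose best score is still too probable returns `+Inf` with a warning: no
window can match. Both strands are scanned; ambiguous bases (N) score
zero log-odds and cannot create a match on their own; occupancy is "any
hit in the peak", the unit the enrichment test counts.

**Enrichment.** One-tailed hypergeometric per motif (`P(X ≥ a)` for `a`
set peaks with the motif out of `m` accessome-wide), with the odds ratio
comparing in-set odds to accessome-wide odds,
`OR = [a/(n−a)] / [m/(N−m)]`; the wording "probability … compared to the
probability" is implemented as this odds ratio, with a relative-risk
variant (`(a/n)/(m/N)`) behind a flag and the choice recorded in the
output. Zero cells get the Haldane 0.5 correction, flagged. BH across
motifs.

**Motif-to-TF assignment.** Candidate motif↔TF associations are resolved
into a minimally redundant one-TF-per-motif assignment by stages: at stage
k, associations to TFs that already have a motif are dropped, then every
motif with ≤ k remaining TFs is assigned, iterating to a fixed point
before k increments. Motifs resolved in the same pass are assigned
simultaneously (two motifs each left with only TF X both become X's
motifs — TFs may end with several motifs; motifs never have more than one
TF). For k > 1 a motif still facing several motif-less TFs goes to the TF
with the fewest remaining candidates (rarest-first, lexicographic
tie-break) — the source describes the widening ("motifs associated with
only two TFs, then three") but not the multi-candidate choice, so the
rule here favors TFs that would otherwise end up motif-less, which is the
stated purpose of the widening. Termination is guaranteed: every pass
either assigns a motif or increments k up to the largest association
count; unresolvable TFs are reported unassigned.

# Motif accessibility deviations

Peaks are first resized to 200 bp around their centers
(`floor((start+end)/2)` in 0-based coordinates, clipped at chromosome
bounds) so each peak contributes a comparable window. For each motif and
sample, observed accessibility sums fragment counts over motif-bearing
peaks; the expected value distributes the motif's grand total over samples
proportionally to library size; the raw deviation is
`(obs − exp)/exp`. Two identities follow from the construction and are
tested: the library-size-weighted mean deviation is exactly zero per
motif, and deviations are exactly invariant to uniform sequencing-depth
rescaling. Rescaling a *single* sample is only approximately neutral —
the pooled expectation itself moves — vanishing as the other samples
dominate the pool.

Background peak sets are sampled with replacement within bins of a 2-D
grid of GC content × mean normalized accessibility (10 quantile bins per
axis, 50 iterations by default; the source names the resampling but not
the matching, which is adopted from the cited algorithm's published
description; an unmatched-uniform mode is available and recorded). The
deviation Z-score is the raw deviation standardized by the mean and sd of
the background deviations; a zero background sd (e.g. all background
draws carrying identical counts) yields NA, flagged. Differential
deviations between sample groups use a Welch t-test for two groups and
one-way ANOVA beyond, BH-corrected, significant at FDR < 0.01; identical
group vectors report p = 1 rather than NaN.

# The synthetic-data generator

`makeFixtures()` emits a complete study bundle — genome FASTA, GFF3 gene
models, chrom.sizes, peaks BED, counts and sample TSVs, DE tables, MEME
motifs, and a truth JSON — that is byte-stable under the config seed (all
RNG kinds pinned). What it emulates, and the defaults:

- **Genome**: 4 chromosomes × 250 kb of i.i.d. sequence at GC 0.40
  (AT-rich, as in tunicate genomes); ~120 gene models with exons and UTRs;
  ~1,500 target peaks seeded at TSS/promoter neighborhoods plus
  intergenic positions, merged through the real accessome code.
- **Design**: the lineage × condition × timepoint grid described above,
  three replicates per cell — controls at 6/10/15/18/20 hpf, mesenchyme at
  10/18, the 10 hpf perturbations, FgfrDN at 15–20 and MRasCA at 18.
- **Counts**: NB with dispersion 0.1 (matching the differential module's
  parameterization so recovery tests are well-posed), base means
  log-uniform in 20–300, library factors log-uniform in 0.6–1.6 to
  exercise normalization.
- **Planted truth**: disjoint peak sets (8 % FGF-opened — which persist,
  so they double as the primed truth —, 5 % FGF-closed, 5 % de novo, 8 %
  lineage-specific), all at |log2FC| = 2, applied only in the
  conditions/timepoints each definition names.
- **Motifs**: a small synthetic catalog of informative PWMs styled after
  the TF families relevant to cardiopharyngeal biology (Fox, GATA, Ets,
  bHLH, T-box, homeodomain; purely synthetic constructs). The Fox motif is
  planted into 80 % of the FGF-opened truth peaks — a realistic rate; not
  every responsive enhancer carries the pathway's motif — by sampling a
  site from the PWM and splicing it into the genome, so re-extracted peak
  sequences carry the sites.

What the generator does *not* emulate: mappability and GC bias in counts,
fragment-size structure, peak-shape heterogeneity, correlated replicates,
chromatin domains, or realistic motif co-occurrence. Passing tests
therefore demonstrate algorithmic correctness and statistical calibration
under the stated model, not robustness to every artifact of real
libraries. The fixture genome is three orders of magnitude smaller than a
real one, and peak density correspondingly higher, which is why the
fixture-scaled pipeline config (`fixturePipelineConfig()`) lowers only the
library-size filter (10,000 instead of 500,000 fragments); every other
threshold keeps its real-data default.

# Numerical choices and degenerate inputs

- Score lattice 1e-3 bits; the DP and the scanner share it exactly.
- GLM fits: IRLS, 50 iterations; non-convergence flags the peak NA.
- Dispersion search on log scale in [1e-8, 30]; working values clipped to
  [1e-8, 10].
- Empty accessome, empty gene sets, all-zero peaks, single-sample
  deviation matrices, motifs longer than their peaks, and degenerate
  binomial nulls (p0 ∈ {0, 1}) all have defined, tested behavior rather
  than errors where a sensible value exists.
- Ties: GSEA ranking is stable (input order preserved among equal
  statistics); the ES extremum breaks exact ties toward the positive side;
  motif assignment breaks ties lexicographically.
- Every stochastic routine takes an explicit seed (default 0) and pins the
  RNG kinds, so results are reproducible across platforms.

# Problem sizes

The test suite and the acceptance script run everything at desk scale:
exact-test oracles enumerate all instances at n ≤ 20 (binomial) and
N ≤ 200 (hypergeometric); PWM thresholds are enumerated exhaustively to
4^8; calibration and recovery simulations use 2,000 peaks at 4 vs 4
replicates; GSEA uses 10,000 permutations for planted-set checks and
1,000-permutation nulls over 200 random sets; the end-to-end pipeline runs
on the default ~1 Mb / ~900-peak / 45-sample bundle. These sizes were
chosen so the whole suite completes in minutes while every estimate they
check is still well-resolved.

# Known limitations

- The QL-F reference makes the test calibrated but slightly conservative;
  exact chi-square behavior is recovered only when dispersions are known.
- Fold changes are unshrunken MLEs: noisy for low-count peaks; rank them
  by p-value, not |log2FC|, when counts are small.
- The peak-permutation GSEA null ignores inter-peak correlation (adjacent
  peaks of one locus are not independent); p-values for sets built from
  few loci with many peaks each are optimistic.
- Deviation Z-scores inherit chromVAR's assumptions: background matching
  corrects GC and mean accessibility only, and the normal approximation of
  the background can be rough for sparse motifs.
- The motif-to-TF multi-candidate rule is one defensible reading of an
  under-specified procedure; alternative tie-breaks change which motif a
  TF receives, not whether it receives one.
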