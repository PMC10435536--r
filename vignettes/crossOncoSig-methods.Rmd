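---
title: "crossOncoSig: methods, parameters, and design choices"
author: "crossOncoSig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crossOncoSig: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

crossOncoSig implements the two workflow shapes used in
signature-driven prognostic subtyping of bulk tumor RNA-seq cohorts,
in the comparative-oncology setting where a signature derived in one
species (canine osteosarcoma) is transferred to another (human) by
shared gene symbol.

* **Workflow A (application)** clusters samples, outcome-blind, in the
  space of an existing signature's genes and then asks whether the
  clusters differ in survival.
* **Workflow B (discovery)** first re-represents the cohort as a
  samples-by-gene-sets enrichment profile (ssGSEA), clusters that
  profile, derives differentially expressed genes (DEGs) between the
  clusters, and mines the DEG-restricted expression matrix for
  gene-sample modules with consensus ISA bi-clustering; each module's
  gene set is exported as a candidate signature and re-applied to an
  independent cohort through Workflow A.

The central structural assumption, enforced by the interfaces rather
than by convention, is **outcome blindness**: no clustering function
accepts a clinical table. Survival enters only after the partition is
fixed, through `assignPrognosisLabels` (post-hoc FP/PP labeling) and
the test layer. This mirrors the design in which prognostic value is a
*finding* about clusters formed from expression alone, not something
the clustering optimizes.

# Preprocessing

**Low-count filter.** `filterLowCounts` applies the `edgeR::filterByExpr`
rule with `min.count = 10`, `min.prop = 0.5`, `large.n = 5`,
`min.total.count = 15`: gene *g* is kept iff its CPM exceeds
`min.count / median(library size) * 1e6` in at least *S* samples, where
*S* equals the smallest group size *n* when *n* ≤ `large.n` and
`large.n + (n − large.n) · min.prop` otherwise, and its total count is
at least `min.total.count`. An optional `keepGenes` whitelist supports
annotation-based restriction (e.g. protein-coding plus polymorphic
pseudogenes) without this package parsing annotation files.

**Collapsing.** Probes mapping to one symbol are averaged
(arithmetic mean per sample); empty or `"NA"` symbols are dropped with
a count. Collapsing is a separate, explicit operation because raw
matrices legitimately carry duplicate probe symbols.

**Normalization.** Workflow A quantile-normalizes the full filtered
matrix before subsetting to signature genes
(`limma::normalizeQuantiles`, average-ties dialect: tied entries
receive the mean of the reference values at their tied ranks). Whether
quantile normalization should act on linear or log-scale values is an
open choice in this design; the package normalizes whatever scale the
input matrix carries and leaves log-transformation to the caller.
Workflow B instead uses TMM scaling factors (`edgeR::calcNormFactors`)
and the prior-damped transform
`log2((count + 0.5) / (libsize · factor + 1) · 1e6)`; the order
filter → TMM → logCPM → collapse matches the intended ssGSEA input
convention.

# Enrichment scoring

**ssGSEA** (`ssgseaScore`). For one sample, genes are ranked by
expression, descending; tied expression receives average ranks for the
weights. With `alpha = 0.25`, the score of set *S* is the sum over all
ranked positions of the difference between the weighted in-set ECDF
(weight of gene *g* proportional to `rank(g)^alpha`, top gene largest)
and the uniform out-of-set ECDF. Scores are normalized by the global
range of the whole samples-by-sets matrix (`normalize = TRUE`), the
customary output normalization. `alpha` and range-normalization
defaults follow the canonical description of the method; both are
arguments. Because the score depends on ranks only, any
rank-preserving transform of a sample leaves its scores unchanged —
one of the property tests asserts exactly this.

**Two-class GSEA** (`gseaTwoClass`). Genes are ranked by
signal-to-noise, `(m₁ − m₂) / (s₁ + s₂)`, with each group SD floored
at `0.2·|mean| + 1e-8` to stabilize near-constant genes. A set's ES is
the maximum deviation of the weighted Kolmogorov–Smirnov running sum
(hit increments proportional to `|metric|^weight`, `weight = 1`). The
null distribution uses phenotype-label permutations when both groups
have at least 7 samples and size-matched random gene sets otherwise —
the usual small-cohort fallback. NES divides ES by the mean |null ES|
of the same sign; nominal p is the same-sign exceedance fraction; the
FDR q follows the positive/negative pooled-null ratio rule, capped at
1. ES computation is `O(|S|)` per set via the hit-position form of the
running-sum extremum; the test-suite checks it against both a full
`O(N)` running-sum walk and an independent implementation (fgsea).

# Clustering and model selection

`kmeansSelectK` runs best-of-`nInit` (default 50) K-means for each
*k* in 2..6 and selects the *k* with the largest mean Euclidean
silhouette width, ties to the smaller *k*; clusters are then relabeled
by decreasing size so labels are stable across runs. Fifty restarts
under a caller seed tame the algorithm's stochastic instability — the
motivating studies report exactly this instability for small
signatures. For Workflow A the feature space is the signature genes'
quantile-normalized expression, per-gene z-scored by default
(`zscoreGenes = TRUE`, heat-map-style standardization; switchable,
since the choice is not dictated by the design). For Workflow B the
feature space is the ssGSEA profile as produced (already globally
range-normalized; per-set z-scoring would inflate the noise sets and
is not applied).

`assignPrognosisLabels` requires *k* = 2 and survival for ≥ 80 % of
clustered samples. The cluster with the longer Kaplan–Meier median is
FP; an undefined median (curve never reaches 0.5) counts as longest;
exact ties label cluster 1 FP with a warning. The partition is never
modified.

`wardClusters` is classic Ward (`hclust` method `"ward.D"` on
Euclidean distances — deliberately the uncorrected variant, matching
the method string of the design it reproduces), cutting gene and
sample trees independently (defaults 10 and 7) to seed ISA.

# Differential expression

`voomTransform` estimates the mean-variance trend voom-style: gene-wise
square-root residual SDs from the ordinary two-group fit are lowess-
smoothed (span 0.5, the canonical default) against average logCPM; the
trend evaluated at each observation's fitted logCPM gives a predicted
sqrt-SD whose inverse fourth power is the observation weight, clipped
to [1e-6, 1e6] (clipping warns — it indicates degenerate residuals). A
constant trend (fewer than two distinct lowess abscissae) falls back to
a flat prediction.

`fitModerated` runs per-gene weighted least squares for the two-group
contrast and applies empirical-Bayes moderation: the prior
(d₀, s₀²) is estimated by moment matching of log-variances
(digamma/trigamma matching to a scaled F distribution — the canonical
estimator), and the posterior variance is
`(d₀·s₀² + d_g·s²_g) / (d₀ + d_g)` with `d₀ + d_g` degrees of freedom
for the moderated t. The estimator degenerating (all variances equal)
falls back to pooled variance (d₀ = ∞) with a warning. `d0` can be
forced: 0 reproduces the ordinary weighted t exactly, ∞ pools all
variances — these limits are asserted in the tests, and the default
estimate is cross-checked against limma's independent implementation
to machine precision.

`selectDegs` applies the published cutoffs strictly: linear fold
change **greater than** 3 (i.e. |log₂FC| > log₂ 3) *and* BH-adjusted
p **less than** 0.05; a gene at exactly 3 is excluded.

# Consensus ISA bi-clustering

`isaNormalize` produces row-standardized (per gene) and
column-standardized (per sample) copies of the matrix. One seeded run
(`isaIterate`) alternates: sample scores = mean of column-standardized
values over the current gene set, z-scored across samples, thresholded
at `tSample`; gene scores = mean of row-standardized values over the
current sample set, z-scored across genes, thresholded at `tGene`;
convergence is two consecutive identical gene and sample sets, with an
iteration cap of 50 (capped runs are flagged and excluded from
consensus).

Parameter choices: `tGene = 2.0` and `tSample = 1.5` sit in the
algorithm's customary operating range (the design this follows states
no values); both are exposed. Thresholding is two-sided by default
(`direction = "signed"`, |z| exceedances), switchable to `"up"`; the
published description does not say which was used, and signed is the
more general reading. Seeding draws 3 random members from each Ward
gene cluster and each Ward sample cluster (17 seeds per run with the
default 10 + 7) — seeding from both axes because the algorithm
requires initial vectors on genes and samples.

`isaConsensus` repeats the fully seeded procedure 25 times with
derived RNG streams, pools converged bi-clusters, matches them
greedily (largest gene set first) by gene-set Jaccard ≥ 0.66 — a
deterministic, order-independent rule after canonical sorting — and
keeps a group only if it spans **strictly more than** 75 % of runs:
with 25 runs, 19 runs accept and 18 reject (0.75 × 25 = 18.75). The
boundary is asserted directly in the tests via
`isaConsensusFromRuns`. Consensus membership is the genes (samples)
present in at least half of the matched instances; output is sorted by
gene-set size.

# Survival statistics

Conventions fixed by this package: the Kaplan–Meier median is the
smallest *t* with S(*t*) ≤ 0.5, undefined if never reached; at tied
times events precede censorings; the log-rank test is the standard
two-group hypergeometric-margins chi-square on 1 df; Cox regression is
univariate partial likelihood with **Breslow** tie handling (the
simplest consistent choice), Wald inference from the observed
information, and monotone-likelihood fits flagged non-converged
(`extra$converged = FALSE`) with the information matrix guarded
against numerical singularity; the chi-square goodness of fit is the
plain Pearson statistic on k−1 df with user-supplied positive expected
counts; the Mann–Whitney U test uses exact enumeration for small
tie-free samples and the tie-corrected normal approximation otherwise.
Censoring is ordinary right-censoring supplied by the user's event
coding — informative censoring (e.g. owner-elected euthanasia in
veterinary cohorts) is *not* modeled; there is no competing-risks
machinery.

# The synthetic cohort generator

`simulateCohort` emulates the statistical structure the pipeline
assumes, at a configurable scale:

* **Cohort shape.** 186 samples (the size of the motivating canine
  trial cohort) by 2000 genes at desk scale; 13,164 genes is the
  full-scale analogue. Two planted sample clusters (A "immune-hot" /
  B "immune-cold"), half the cohort each.
* **Expression.** Per-gene baseline log₂ means Normal(5, 2); a planted
  prognostic module of 270 genes (the size of the larger published
  signature analogue) up-shifted in cluster A by `moduleLog2fc`;
  counts negative binomial with Var = μ + φμ², φ = 0.15 — typical of
  bulk tumor RNA-seq and large enough to make precision weights
  informative; library sizes log-normal around 3·10⁷, emulating
  44–61 million pass-filter reads.
* **`moduleLog2fc = 2.0` (fold change 4).** The workflow's own DEG
  cutoff is fold change > 3. A planted effect below that cutoff could
  never be recovered by the pipeline's published threshold no matter
  the sample size — the per-gene calling probability would be bounded
  below one half — so the generator plants its module comfortably
  above the threshold it is meant to exercise. This is a design-time
  power calculation, not a tuned value.
* **Planted bi-cluster blocks** are nested in the prognostic
  structure: block genes are drawn from the module, block samples from
  cluster A (defaults: 40×45 and 30×35 at +1.5 log₂ units). The
  placement is structural, not cosmetic: ISA column-standardizes the
  analysed matrix, so a shift shared by *every* gene of the DEG
  universe is invisible to it; discoverable ISA structure is by
  necessity *sub*-structure of the DEG set — which is exactly how the
  motivating analysis found granular immune sub-signatures inside its
  DEG universe.
* **Survival.** Exponential event times with hazard 1/300 per day in
  cluster A and hazard ratio 2 for cluster B; independent
  administrative censoring by a Uniform(0, h) horizon with h solved
  (by `uniroot` on the closed-form censoring probability) to hit the
  target censoring fraction, 25 % by default.

What the generator does **not** emulate: batch effects, gene-length
bias (TPM inputs are taken as-is), cross-species ortholog divergence
(transfer in the synthetic tests is same-universe), informative
censoring, correlated gene-gene noise beyond the planted blocks, and
annotation ambiguity beyond simple duplicate symbols. Passing tests
therefore demonstrate the machinery recovers planted structure under
NB noise at realistic depth — not that any particular real cohort
analysis is correct.

# Numerical choices and degenerate inputs

* Ties: average ranks in ssGSEA weights and quantile normalization;
  K-means silhouette ties go to smaller *k*; FP/PP median ties go to
  cluster 1 with a warning.
* Strictness: DEG bounds and the ISA consensus fraction are strict
  inequalities, asserted at their boundaries in the tests.
* Degenerate inputs: constant feature matrices, all-filtered count
  matrices, zero-library samples, constant Cox covariates, sets
  covering all genes, and empty seeds raise located errors; empty
  intersections and undersized seed clusters warn and proceed.
* Reproducibility: every stochastic function takes a seed and restores
  the caller's RNG state; pipeline stages draw deterministic child
  seeds (kept below 2³¹) from the root seed, so stages are
  independently reproducible and full reruns are bit-identical.

# Problem sizes in the test-suite

The suite and the acceptance script run at desk scale by choice: the
default synthetic cohort is 186 × 2000 (module 270), ISA recovery uses
a 500 × 150 matrix with four planted blocks, log-rank calibration uses
1000 null replicates at n = 100 and power at n = 150, Cox recovery 100
cohorts of n = 200, and the moderated-t calibration 10 NB cohorts of
1000 genes. These sizes give the planted-truth assertions comfortable
statistical margins while keeping a full run in the order of a minute.

# Known limitations

* Two-group designs only: no multi-factor linear models, no duplicate
  correlation, no robust empirical Bayes.
* No batch correction; cohorts entering a transfer are normalized
  independently (per-cohort quantile normalization), matching the
  intended cross-cohort convention, and no joint renormalization is
  attempted.
* Signature transfer is by uppercased symbol intersection; genes
  without a shared symbol are reported dropped, never remapped through
  orthology resources.
* ISA consensus can split a noisy module into overlapping variants
  when run-to-run instances straddle the Jaccard matching threshold;
  the matching threshold (0.66) and thresholds t_gene/t_sample are the
  knobs to adjust.
* GSEA leading-edge reporting and enrichment plots are out of scope.
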