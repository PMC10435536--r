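# crossOncoSig

Prognostic gene-signature discovery and cross-cohort transfer for bulk
RNA-seq, built around the comparative-oncology setting in which
signatures derived in canine osteosarcoma are applied to human cohorts
(and vice versa) by shared gene symbol.

## Who this is for

Computational biologists analyzing clinically annotated tumor
expression cohorts who want to (a) apply an existing gene signature to
stratify patients and test whether the resulting clusters differ in
survival, or (b) derive new prognostic signatures de novo from one
cohort and validate them in an independent — possibly cross-species —
cohort, with every stochastic stage reproducible from a single seed.

## What it computes

Two companion workflows, mirrored on the standard design of
signature-driven tumor subtyping studies:

**Workflow A — signature application** (`runSignatureWorkflow`):
low-count filtering (edgeR's `filterByExpr` rule: keep gene *g* iff
CPM_g ≥ 10/median(lib)·10⁶ in enough samples and total count ≥ 15) →
probe collapsing → quantile normalization → symbol harmonization →
outcome-blind K-means over the signature genes with the number of
clusters *k* ∈ {2..6} chosen by maximum mean silhouette → post-hoc
favorable/poor-prognosis (FP/PP) labeling by Kaplan–Meier median →
log-rank tests per endpoint → two-class GSEA and moderated-t
differential expression between the clusters.

**Workflow B — signature discovery** (`runDiscoveryWorkflow`):
filtering → TMM → log₂CPM → single-sample GSEA (ssGSEA) over a
hallmark-style gene-set collection, scoring each sample *j* and set *S*
by

  ES(j,S) = Σ_i [ P_in(i) − P_out(i) ],
  P_in(i) = Σ_{g≤i, g∈S} r_g^α / Σ_{g∈S} r_g^α,
  P_out(i) = #{g≤i, g∉S} / (N − |S|),

over the descending expression ranking (α = 0.25) → K-means on the
enrichment profile → voom-style precision-weighted moderated-t
differential expression (empirical-Bayes shrinkage
s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), BH correction, DEG cutoffs
fold change > 3 and adjusted p < 0.05) → consensus bi-clustering of the
DEG-restricted matrix with the Iterative Signature Algorithm (ISA):
Ward-seeded (10 gene / 7 sample clusters, 3 random members per seed),
alternating z-thresholded updates (t_gene = 2.0, t_sample = 1.5) to a
fixed point, 25 stochastic repetitions, and a strict > 75 % consensus
filter (≥ 19 of 25 runs) — one exported gene signature per consensus
bi-cluster, plus the DEG-derived signature, each re-applied to a second
cohort via Workflow A.

Survival statistics (Kaplan–Meier product-limit, log-rank, univariate
Cox with Breslow ties, chi-square goodness of fit, Mann–Whitney U) are
exposed directly, as are all the pipeline stages
(`filterLowCounts`, `quantileNormalize`, `tmmFactors`, `logCPM`,
`ssgseaScore`, `gseaTwoClass`, `kmeansSelectK`, `wardClusters`,
`voomTransform`, `fitModerated`, `selectDegs`, `isaConsensus`, ...).

A synthetic-cohort generator (`simulateCohort`, `simulateGenesets`)
emits negative binomial counts with a planted immune-hot/cold
prognostic module, planted gene–sample bi-cluster blocks, and
cluster-linked exponential survival, so the whole pipeline can be
validated against known ground truth without any data download.

## Worked example

```r
library(crossOncoSig)

sim  <- simulateCohort(simConfig(), seed = 11)          # 186 x 2000 cohort
sets <- simulateGenesets(nSets = 50, sizeRange = c(30, 200),
                         genes = geneIds(sim$counts),
                         aliasModule = sim$truth$moduleGenes, seed = 12)
validation <- simulateCohort(simConfig(), seed = 13)    # independent cohort

report <- runDiscoveryWorkflow(
  sim$counts, sim$clinical, sets, seed = 14,
  secondCohort = list(counts = validation$counts,
                      clinical = validation$clinical))

report$ssgsea_clustering
#> ClusteringResult on ssgsea-scores: k = 2 selected from {2,3,4,5,6}
#>   mean silhouette by k: 2=0.673  3=0.362  4=0.048  5=0.044  6=0.044
#>   cluster sizes: 93, 93

report$degs
#> GeneSignature 'discovery-DEGs': 269 genes
#>   GENE00006, GENE00007, GENE00008, GENE00012, GENE00015, ...

report$biclusters[[1]]
#> Bicluster: 35 genes x 35 samples (support 1.00)

report$transfer[["discovery-DEGs"]]$logrank[["OSv"]]
#> TestResult [logrank_chi2]: statistic = 16.1, df = 1, p = 6.021e-05
```

The silhouette criterion selects two enrichment-profile clusters of 93
samples each (the planted immune-hot/cold split); the moderated-t
contrast between them yields a 269-gene signature that is essentially
the planted 270-gene module; ISA then isolates the planted
co-expression sub-blocks inside it; and the signature, re-applied to
the independent validation cohort, produces an FP/PP split whose
overall-survival curves separate at log-rank p ≈ 6×10⁻⁵.

The classic worked example of comparing an observed two-group patient
split against a reference composition:

```r
chisqGof(c(5, 15), c(6.3, 13.7))
#> TestResult [pearson_chi2]: statistic = 0.3916, df = 1, p = 0.5315
```

## Documentation

The methods vignette (`vignettes/crossOncoSig-methods.Rmd`) describes
the models, the parameter choices and their defaults, what the
synthetic cohorts do and do not emulate, and known limitations.
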