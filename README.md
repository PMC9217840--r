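# svzmeth

DNA-methylome classification of subventricular-zone (SVZ) associated
glioblastoma, with multi-omic characterization of the resulting classes.

## The problem

Glioblastomas in contact with the subventricular zone — the neural-stem-cell
niche along the lateral ventricles — carry a worse prognosis, but calling a
tumor "SVZ+" from MRI alone is subjective: raters disagree often, and
peripheral tumors that secondarily infiltrate the niche are easily
misread as SVZ-derived. `svzmeth` implements a molecular alternative: a
small CpG methylation signature (SVZM) derived from 450K-style
beta-value arrays, together with the survival, copy-number, mutational
and transcriptomic analyses used to validate and characterize the two
methylome classes.

The package is aimed at statisticians and computational biologists who
want a tested, seedable implementation of this workflow — either to run
it on their own methylation cohorts (TSV matrices of beta values plus a
sample sheet) or to study its statistical behavior on the built-in
synthetic cohort generator, which plants a known truth in every data
layer.

## What it computes

**Signature discovery** (training cohort, MRI-labelled):

1. probe filtering (sex chromosomes, SNP overlap, repeats), M-values
   `M = log2(beta / (1 - beta))`, optional top-30,000 MAD preselection;
2. per-CpG Welch t-tests on M-values; DMPs at `p < 0.001`;
3. greedy clustering-stability pruning of the DMP set (2-cluster
   hierarchical clustering, Euclidean/complete, leave-one-probe-out);
4. random-forest ranking (mean decrease in Gini impurity, 500 trees);
5. the top-15 CpGs form the signature; 2-cluster HCL of the training
   samples fixes the centroids, oriented by MRI majority.

**Classification**: new cohorts are clustered over the signature probes
(Chebyshev distance, ward.D, cut at 2) and oriented by proximity to the
training centroids; a direct nearest-centroid mode is also available.

**Characterization**: Kaplan–Meier / Cox PH (Efron ties) / Weibull AFT
with likelihood-ratio tests; chi-squared / Fisher / Barnard (Z-pooled,
unconditional) contingency tests; Goodman–Kruskal lambda, ICC(2,1),
consensus rating across MRI raters; CBS-style copy-number segmentation
with MAD-based automatic gain/loss thresholds; multi-pipeline mutation
consensus (≥3 of 4 callers) with per-gene Barnard enrichment, Wilcoxon
burden tests and a mutation-type × class mixed model; SAM-style
permutation-FDR differential methylation with cross-cohort consensus;
expression t-tests, methylation–expression Pearson correlation,
negative-binomial count models with library-size offsets, and weighted
pathway-activity scores.

## A worked example

```r
library(svzmeth)

# a training cohort at the study design: 24 SVZM+ vs 30 SVZM- samples,
# 200 planted DMPs among 10,000 CpGs, 1.5 M-value units apart
train <- generate_cohort(sim_config(n_pos = 24, n_neg = 30,
                                    n_probes = 10000, n_dmp = 200,
                                    effect_delta = 1.5, seed = 101))
disc <- discover_signature(train$methylation, train$truth$labels, seed = 7)
length(disc$signature$probes)
#> [1] 15
mean(disc$signature$probes %in% train$truth$dmp_ids)
#> [1] 1

# an independent validation cohort sharing the planted structure
valid <- generate_cohort(sim_config(n_pos = 60, n_neg = 72,
                                    n_probes = 10000, n_dmp = 200,
                                    effect_delta = 1.5, seed = 102),
                         template = train, sample_prefix = "V")
labels <- classify_svzm(valid$methylation, disc$signature,
                        "validation_clustering")
mean(labels == valid$truth$labels[names(labels)])
#> [1] 1

# survival contrast of the two classes
valid$samples$svzm <- as.integer(labels[valid$samples$sample_id] == "SVZM+")
cox_fit(valid$samples, "svzm")
#> SurvivalFit (coxph): LRT p = 0.001913
#>        coef     HR lower95 upper95      p
#> svzm 0.7357 2.0869  1.3132  3.3164 0.0019
```

The fitted hazard ratio (~2.1 here) estimates the planted log hazard
ratio of 0.91 (true HR ≈ 2.48); the signature contains only planted
differential CpGs, and the validation cohort is classified in full
agreement with its simulated ground truth.

The whole two-cohort workflow (simulate → preprocess → discover →
classify → survival / agreement / CNV / mutations / integration) is also
available as stages with JSON manifests:

```r
cfg <- pipeline_config(out_dir = "svzm_run", seed = 1)
run_pipeline(cfg)
```

or from a shell via `Rscript inst/scripts/svzm-pipeline.R --stage all
--out svzm_run --seed 1`.

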