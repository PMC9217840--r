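---
title: "Methylome-based SVZ classification: models, parameters and design choices"
author: "svzmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome-based SVZ classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`svzmeth` derives a small CpG methylation signature that separates
IDH-wildtype glioblastoma by subventricular-zone association (the SVZM
classes), applies it to new cohorts by hierarchical clustering, and
characterizes the classes on survival, copy-number, mutational and
transcriptomic data. This vignette documents the statistical models, the
parameters that matter, the synthetic-data generator that the test suite
exercises, and the design choices made where the procedure was genuinely
open. It states no empirical claim that the test suite and
`scripts/acceptance.R` do not themselves recompute.

# Preprocessing

Input is a CpG × sample matrix of beta values (methylated fraction, in
(0,1)) with per-probe annotation. Probes on sex chromosomes, overlapping
SNPs, or in repetitive sequence are removed before any analysis —
sex-chromosome probes confound with patient sex, SNP probes confound
genotype with methylation, repeats cross-hybridize. Analyses run on
M-values, `M = log2(beta/(1-beta))`, whose variance is more nearly
constant across the beta range. Beta values are clipped to
`[1e-3, 1 - 1e-3]` at load time so M is always finite; the clip count is
reported. Array normalization from raw intensities is out of scope: the
package starts from normalized beta values and provides a no-op hook
where a normalization step would sit.

For global clustering views, the top 30,000 probes by raw median
absolute deviation of beta (median of absolute deviations from the
probe median, no consistency constant — the plain robust spread, not a
sigma estimate) can be preselected with `top_mad_probes()`. Ties are
broken by probe id so the selection is reproducible. The classifier
branch filters flagged probes *first* and applies MAD selection second;
the order is fixed in `discover_signature()` and stated here because
beta-value spread on sex-chromosome probes would otherwise dominate the
selection.

# Signature discovery

Four stages, each testable on planted truth:

1. **Differential methylation.** Per-CpG Welch two-sample t-tests on
   M-values between the MRI-labelled classes; probes with `p < 0.001`
   (parameter `alpha_dmp`) are the DMP set. Welch rather than a pooled-
   variance or moderated test: the two MRI groups are small and there is
   no reason to assume equal variances; the choice is surfaced as a
   documented default rather than buried. Zero-variance probes get an
   epsilon-stabilized statistic and are flagged.
2. **Stability pruning.** The published derivation — selecting probes by
   the least stable classification error of hierarchical clustering —
   does not pin down an algorithm, so the package implements a
   deterministic greedy rule: repeatedly 2-cluster the samples
   (Euclidean distance, complete linkage) with each single probe left
   out and drop the probe whose removal yields the lowest
   misclassification against the MRI labels, as long as that does not
   increase the current error. While the error is positive, lateral
   moves are allowed — among removals tied at the lowest error the least
   label-discriminative probe (smallest |Welch t|) is dropped, so
   label-scrambled probes that merely destabilize the clustering leave
   first. Pruning stops the moment the clustering classifies perfectly
   (a separating probe set is never thinned further) or when every
   removal would strictly worsen the error. A strict-improvement-only
   variant was rejected: on data where disruptive probes dominate the
   clustering, no *single* removal improves the error, and strict greedy
   would keep the entire disruptive set. This is a stated
   interpretation, not a reconstruction of the original unpublished
   procedure.
3. **Random-forest ranking.** 500 trees, `sqrt(p)` candidate features per
   split, mean-decrease-in-Gini importance, mandatory seed. Ties broken
   by probe id.
4. **Signature.** The top `k = 15` probes. The training samples are
   2-cluster clustered over these probes; the cluster with the MRI SVZ+
   majority is labelled SVZM+, and both cluster centroids (mean M
   vectors) are stored. A majority tie raises an error rather than
   guessing polarity.

**Classification of new cohorts** clusters samples over the signature
probes with the Chebyshev ("maximum") distance and ward.D linkage, cut
at two clusters — the combination used for the independent validation
cohort — and orients the two clusters by total squared distance of their
mean M-vectors to the stored training centroids (the two clusters always
receive distinct labels). Training-recipe clustering
(Euclidean/complete) and direct nearest-centroid assignment are also
available. Centroid proximity, rather than re-running an MRI majority
vote, is used away from the training cohort because validation cohorts
need not carry MRI labels at all.

# Survival models

`cox_fit()` wraps a maximum partial-likelihood Cox model with Efron
handling of ties (the default of the survival ecosystem this analysis
family uses), Wald 95% intervals, and a likelihood-ratio test against
the null model. `weibull_fit()` is a Weibull accelerated-failure-time
model with right censoring; the AFT coefficient `b` is also reported on
the proportional-hazards scale as `HR = exp(-b * shape)`. Parametric
fits matter here because the cohorts are small; for the same reason
`multivariable_cox()` refuses to fit below 5 events per variable unless
forced. The test suite checks the Cox coefficient against a hand-coded
partial-likelihood grid search, Kaplan–Meier output against the raw
product-limit computation, and the Weibull likelihood at the optimum
against random parameter probes.

# Categorical and agreement statistics

Contingency tests follow the R conventions under which the printed
training-cohort characteristics table reproduces exactly: Yates
continuity correction on 2×2 tables only (with the `max(|O-E|-0.5, 0)`
safeguard), none on larger tables, and "Unsure" rows kept as ordinary
categories. `barnard_test()` is the unconditional exact test with the
Z-pooled score statistic, two-sided `|Z|` ordering, and a deterministic
maximization over 1001 equally spaced nuisance probabilities in (0,1) —
the common default among Barnard variants, stated because the name alone
does not fix one. It is written from scratch (no installed package
provides it) and is verified against an independent enumeration oracle.
Inter-rater agreement uses ICC(2,1) — two-way random effects, absolute
agreement, single rater — computed from ANOVA mean squares with the
Shrout–Fleiss F-based interval; which ICC variant produced the published
agreement value is not stated there, so the variant is a surfaced
choice, not a claim. Goodman–Kruskal lambda gets a seeded percentile
bootstrap CI (2000 resamples). Consensus MRI rating demands unanimity
among non-missing raters.

# Copy number

Probe-level log2 ratios are segmented per chromosome by recursive binary
splitting: the split maximizing the two-sample t-statistic is accepted
when its within-segment permutation p (199 seeded permutations) falls
below `alpha_split = 0.01` and both sides keep `min_probes = 5` probes.
This is a deterministic, seeded stand-in for the segmentation the
dedicated 450K CNV packages perform; it is not a reimplementation of any
of them, and the acceptance of a split is the only stochastic element.
Gain/loss thresholds come from a normal-tissue reference: median ± 2.5
MAD (1.4826 constant) of the reference segment means — a robust
symmetric band; the reference panel ships with the synthetic bundle.
Coordinates are 0-based half-open throughout, so segment output is
BED-compatible. Class comparison assigns each sample's state per genomic
bin from the segment covering the bin midpoint and runs a Fisher test of
altered-vs-neutral against class per bin.

# Mutations

Calls from several pipelines are reduced to a per-(sample, gene)
consensus: mutated iff ≥ `min_pipelines` (default 3 of 4) pipelines
report a non-silent call. Silent calls never count toward mutation
status. Per-gene class enrichment uses Barnard's test on the 2×2
mutated × class table, with genes mutated in exactly one class flagged
exclusive; per-sample burden is compared by two-sided Wilcoxon rank-sum.
The mutation-type × class interaction is a linear mixed model on
per-sample, per-type, per-pipeline counts — `count ~ type + type:class`
with a random intercept per calling pipeline (REML, Satterthwaite
Wald tests) — so that between-pipeline level differences are absorbed by
the random effect rather than inflating the class contrasts. Counts are
the default response (presence/absence is available); a singular random
effect falls back to fixed effects with a warning.

# Integration

`sam_test()` implements the moderated permutation test: `d_i = r_i /
(s_i + s0)` with `r_i` the M-value mean difference, `s_i` the pooled
standard error and `s0` the median of the `s_i` — a deterministic
simplification of the original coefficient-of-variation minimization for
the fudge factor, chosen so the whole procedure is reproducible from a
seed; its FDR behavior is verified empirically by the null-calibration
tests rather than assumed. Seeded label permutations give expected order
statistics; probes beyond `delta` from them are called; the FDR at a
threshold is the median permutation count of exceedances over the called
count, and the smallest `delta` meeting the target FDR (default 0.05,
500 permutations) is selected. Cross-cohort consensus intersects called
sets and *requires direction concordance* — a bare intersection could
pair a hypo- with a hypermethylated call of the same probe, which is not
evidence of a shared signal.

Expression analyses run on `log2(CPM + 1)` transformed counts. This
replaces a variance-stabilizing regularized-log transform: it preserves
monotonicity and damps the variance of low counts, and every place the
transform enters (t-tests, correlations, pathway scores) is tested on
planted effects under it. Count-level class tests are negative-binomial
regressions with a `log(total counts)` offset (method-of-moments
dispersion refined by maximum likelihood; moments kept if ML fails); the
reported p is one-sided for *decreased* expression in SVZM+, matching
the expected direction for hypermethylated signature genes, and
configurable. Pathway activity is a weighted sum of z-scored transformed
expression over a user-supplied weight table (a small synthetic fixture
ships under `inst/extdata/`; redistributing trained weight matrices is
out of scope), contrasted between classes by a linear model.

# The synthetic cohort generator

`generate_cohort()` draws every layer from one seeded generator with a
sub-stream per layer, so editing one layer never perturbs another:

- **Methylation**: per-CpG beta distributions with concentration
  `beta_dispersion = 50` (typical array-scale noise: sd ≈ 0.07 at
  mid-range beta). Baselines are bimodal (most CpGs near 0.1 or 0.9,
  as on real arrays); planted DMPs sit mid-range (0.35–0.65). The
  planted shift `effect_delta` defaults to 1.5 on the M-value scale
  (`effect_scale = "m"`; a beta-scale shift is available), applied
  symmetrically ±delta/2, with `frac_hypo = 0.98` of DMPs
  hypomethylated in SVZM+ — the strong hypomethylation asymmetry the
  analysis is designed to detect, with the remaining minority
  hypermethylated like the signature's nested-gene-pair probes.
- **Design**: 24 SVZM+ vs 30 SVZM− samples by default, the training
  design; validation cohorts reuse the planted structure through the
  `template` argument (132 samples, 60/72, in the pipeline default).
- **Survival**: Weibull baseline (shape 1.4, scale 18 months — median
  near 14 months for the reference class, the expected scale for this
  disease) with proportional hazards `log_hr = 0.91` (HR ≈ 2.48) on the
  class indicator. Censoring: each subject is independently censored
  with probability `censor_rate = 0.3` at a uniform fraction of its
  event time, so the realized censoring fraction is calibrated to the
  parameter by construction.
- **Expression**: negative-binomial counts (size 10) over a 2000-gene
  universe; genes mapped to planted CpGs have a latent Gaussian
  log-mean correlated at `coupling_rho = -0.7` with the CpG's M-value.
  Coupled genes are kept a small fraction of the library so that
  library-size normalization does not absorb the shared class signal.
- **CNV**: 100 probes per chromosome, probe noise sd 0.15; default
  events are a chromosome-10 loss (penetrance 0.7) and a chromosome-19
  gain (0.6) in the negative class; a 30-sample normal reference panel
  accompanies the tumors.
- **Mutations**: per-gene, per-class Bernoulli rates (defaults include
  one gene enriched in each class and one exclusive to SVZM+), 15%
  silent, observed by 4 pipelines with sensitivity 0.9 and false-call
  rate 0.01 — the regime in which the ≥3-of-4 consensus has sensitivity
  `P(Bin(4, 0.9) ≥ 3) ≈ 0.948`.
- **Raters**: 2–3 raters flip the true label independently with
  `rater_error` (default 0.15). No noise model for MRI rating is given
  anywhere authoritative; the flip probability is a free parameter, and
  the sample sheet's MRI label is the rater majority.

What the generator does *not* emulate: Illumina type I/II probe
chemistry, batch and FFPE artifacts, tumor purity, spatially correlated
CNV noise, mutation signatures, or rater biases that correlate between
raters. Passing tests therefore demonstrate the statistical machinery
recovers planted structure under the stated noise models — not that the
pipeline is robust to every artifact of real arrays.

# Numerical choices and degenerate inputs

- Beta clipping 1e-3; epsilon-stabilized t statistics for zero-variance
  probes (flagged, p = 1 when means coincide).
- All tie-breaks (MAD selection, RF importance, gene ranking) are by
  lexicographic id, making every ranking total and reproducible.
- Barnard's maximization uses a fixed grid, so p-values are exactly
  reproducible; p is clamped to (0, 1].
- Cluster orientation ties (exactly equal MRI majorities) and empty
  probe sets after filtering raise errors instead of silent defaults.
- `sam_test` evaluates every candidate delta (the observed gaps), so
  the called-set path is monotone in delta by construction.
- Problem sizes in the test and acceptance suites — 10,000 probes for
  discovery, 2,000 for SAM with 100 permutations, 200 Cox replicates at
  n = 300 — are the package's chosen desk-scale study conditions: large
  enough that the planted-recovery criteria are sharp, small enough to
  run routinely.

# Known limitations

- The published 15 CpG identities, the 439-probe consensus, and the
  cohort-specific gene lists cannot be reproduced here: the underlying
  per-patient data are not redistributable, so all quantitative checks
  run on synthetic cohorts with planted truth.
- The stability-pruning rule is one deterministic reading of an
  under-specified derivation step; other readings (e.g. cross-validated
  error) could retain different probe subsets.
- The segmentation is a seeded approximation, not the referenced CNV
  package's algorithm; thresholds are a robust stand-in for its
  automatic selection heuristic.
- The mixed model treats per-type counts as Gaussian; for very sparse
  types a count GLMM would be preferable but is harder to keep stable
  across the small cohorts this targets.
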