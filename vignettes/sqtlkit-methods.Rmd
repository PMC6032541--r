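---
title: "Models and methods behind sqtlkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sqtlkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqtlkit)
```

sqtlkit maps three classes of cis expression QTLs from genotype dosages and
RNA-seq count matrices — splicing QTLs (sQTLs, via exon inclusion and intron
excision ratios), exon expression QTLs (eeQTLs) and gene expression QTLs
(geQTLs) — and then asks whether the same local genetic signal acts across
tissues, using local genomic relationship matrices and a summary-statistic
meta-analysis. This vignette explains each model, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## Phenotype construction

Raw evidence enters as three count matrices per tissue: gene counts, exon
counts, and intron junction counts. Features with CPM > 0 in no more than
40% of samples are removed (`filter_expressed()`; the inequality is strict,
so a feature expressed in exactly 40% of samples is dropped). Two ratio
phenotypes are derived:

* **inclusion** — exon CPM divided by parent-gene CPM (`inclusion_ratio()`).
  Computing both sides on the CPM scale makes per-sample sequencing depth
  cancel identically; entries with a zero gene count are missing, never 0
  or infinite.
* **excision** — each intron junction's count over the total of its cluster
  (`excision_ratio()`). A cluster is all junctions assigned to one gene;
  within a sample, cluster ratios sum to 1 wherever the total is non-zero.
  The package does not re-cluster junctions from alignments: clusters come
  from the annotation (or the simulator), a deliberate simplification of
  alignment-based intron clustering.

Ratios below 0.001 are set missing. The threshold is applied **per entry**,
one of two defensible readings (the alternative, dropping whole features by
their mean, removes more data than the filter needs to); the choice is
logged at run time. Remaining values are log2 transformed, each feature is
mapped onto standard normal quantiles by its ranks (offset-0.5 plotting
positions, ties to average ranks — deterministic and standard), and each
sample is z-scored over its non-missing entries. Expression phenotypes take
the same route starting from log2-CPM with a 0.5 pseudocount.

Two points deserve emphasis:

* "Quantile normalisation" is implemented as the per-feature rank-based
  inverse-normal transform, because every downstream model assumes Gaussian
  phenotypes. A pooled-distribution variant (all features mapped onto the
  common empirical distribution) is available behind
  `common_distribution = TRUE` for users who read the term the other way.
* Observation-level precision weights (the mean–variance trend weighting
  used by some expression pipelines) are **not** computed. Weights interact
  with the rank-based chain in an unspecified way, and the package's
  validation surface — parameter recovery on synthetic data — does not
  require them; all observations are weighted equally.

The chain is invariant to per-sample library-size scaling up to tie
handling: the pseudocount can reorder entries that differ by less than
0.5 reads, so exact invariance holds for counts that are distinct at that
resolution (the tests construct such fixtures deliberately).

Features left with fewer than 3 non-missing values, or with zero variance
(e.g. a constant ratio, which carries no rank information), are dropped
with a warning.

## Differential splicing

Across tissues, each inclusion/excision phenotype is fitted with the mixed
model

\[ y = \text{animal}_{(random)} + \text{experiment} + \text{tissue} + e \]

by REML, and the tissue term is tested with an F statistic using
Satterthwaite denominator degrees of freedom (`tissue_mixed_model()`, via
lme4/lmerTest). The animal random effect absorbs repeated measures of the
same animal across tissues. Two numerical choices: the tissue test is the
marginal (Type III) test — with no interactions in the model this equals
the Type II test, so the unstated choice is inconsequential — and when
every animal is observed exactly once the random effect is structurally
unidentifiable, so the model is fitted directly by OLS, to which it reduces
exactly; the test suite verifies F agreement to 1e-6. Between breeds
(two levels), a per-feature OLS fit is used, equivalent to the equal-variance
two-sample t-test.

A gene is called differentially spliced only under a **conjunction**: at
least one exon significant at FDR < 0.1 *and* at least one intron adjacent
to that exon significant at FDR < 0.1, with the FDR computed separately
within the exon and intron analyses (Storey q-values; pi0 from a df-3
smoothing spline on the 0.05–0.95 lambda grid, BH available behind a flag).
The effective combined threshold is reported as 0.1 × 0.1 = 0.01.
"Adjacent" is not defined in most descriptions of this design; sqtlkit uses
boundary sharing (intron start = exon end + 1, or intron end = exon
start − 1) and falls back to the nearest same-gene intron within 10 kb,
recording which rule fired for every call. Gene ranking for downstream
export uses the minimum product of exon and intron q-values per gene.

## Cis QTL scans and the sQTL conjunction

`scan_cis()` tests every SNP within ±1 Mb of a feature against that
feature's phenotype by OLS on allele dosage, optionally with covariates
(breed, for stratified designs). The window is anchored at the feature
*boundaries* (start − 1 Mb, end + 1 Mb) rather than the midpoint: "within
or up to 1 Mb away" reads naturally as distance from the feature, and
boundary anchoring is the permissive interpretation. Missing phenotype
entries are excluded pairwise and never imputed; a pair with fewer than
(number of covariates + 3) complete observations is skipped. Only the
additive dosage term is fitted — no dominance. q-values are computed within
one scan (one tissue × one phenotype class), never pooled across tissues.

An sQTL call again requires a conjunction at the SNP level: the SNP passes
FDR < 0.1 for an exon's inclusion ratio *and* FDR < 0.1 for the excision of
an intron adjacent to that same exon (`call_sqtls()`). eeQTLs and geQTLs
use a single FDR < 0.01 filter on the exon/gene expression scans
(`classify_qtl_types()`). These two stringencies are deliberately
asymmetric — the conjunction of two 0.1 filters and a single 0.01 filter
are not comparable error rates; the package implements the design as
printed and documents the asymmetry rather than harmonising it.

## Local genomic relationship matrices and bivariate REML

To ask whether a feature's phenotype in two tissues is driven by the same
cis variation, SNPs within ±1 Mb form a local GRM (`build_lgrm()`). The
default construction is the centred cross-product scaled by the summed
heterozygosity (VanRaden's first method), chosen for its closed-form
testability; per-SNP standardisation (GCTA-style) is available behind
`method = "gcta"`. Monomorphic SNPs are excluded, at least 10 polymorphic
SNPs are required, and a 1e-6 ridge keeps small local windows invertible.
The genetic correlation is scale-free, so the choice of GRM scaling does
not move the estimand.

`bivariate_reml()` fits the two-trait model \(y = \mu + a + e\) with
\(\mathrm{cov}(a)\) structured by the local GRM and reports

\[ r_{lg} = \frac{\mathrm{cov}_g(tr_1, tr_2)}
                {\sqrt{\mathrm{var}_g(tr_1)\,\mathrm{var}_g(tr_2)}} , \]

with a delta-method standard error from the average-information matrix.
Numerical strategy:

* **AI-REML on the natural (co)variance scale** with step-halving when a
  proposed update is out of bounds or decreases the restricted likelihood,
  and an EM fallback step for the variances. Variances are floored at
  1e-6 of the phenotypic variance; covariances are clamped strictly inside
  their Cauchy–Schwarz bound (factor 0.99995) so the covariance matrix
  stays invertible even when the true correlation is 1.
* Fits that stall at the correlation boundary (the likelihood surface
  becomes a ridge as \(r \to 1\)) are finished by a simplex polish on the
  transformed scale — log variances, atanh-bounded correlations — which
  handles the boundary smoothly. An earlier design ran the whole
  maximisation on the transformed scale; the hybrid keeps the information
  matrix directly interpretable for the standard error while inheriting
  the transformed scale's boundary behaviour.
* Accepted iterations never decrease the restricted likelihood (tested).
* Designs with no shared individuals cannot identify a residual
  covariance, so it is structurally fixed at 0 (and logged); shared-sample
  designs estimate it by default.
* A genetic variance estimated at its boundary makes \(r_{lg}\) undefined;
  it is reported missing rather than as a ±1 artefact.

`test_rg()` refits with \(r\) fixed at 0 or 1 and refers twice the
log-likelihood difference to \(\chi^2_1\). The \(r = 0\) null is interior,
so the plain \(\chi^2_1\) applies (and is verified to be uniform under
null simulations); \(r = 1\) is a boundary, where the reference is the
50:50 mixture of a point mass at zero and \(\chi^2_1\).

## Meta-analysis and overlap

Three summary-statistic devices:

* **Two-cohort weighting** (`weighted_t()`): inverse-variance combination
  of per-SNP effects estimated separately in cohorts with different
  phenotypic error (bulls vs cows): \(B_w = (B_1/se_1^2 + B_2/se_2^2) /
  (1/se_1^2 + 1/se_2^2)\), \(se_w^{-2} = se_1^{-2} + se_2^{-2}\),
  \(t_w = B_w / se_w\). With equal SEs this is \((t_1 + t_2)/\sqrt 2\).
  Where both devices are used, weighting is applied per trait first and
  the multi-trait statistic is formed on the weighted t values.
* **Multi-trait statistic** (`multitrait_chisq()`): \(t' V^{-1} t\) on the
  per-trait signed t values, \(\chi^2\) with one df per trait. \(V\) is
  the empirical correlation of t values over SNPs, estimated from SNPs
  with |t| < 2 in every trait so that true signals do not inflate it; the
  truncation attenuates strong correlations slightly, which is the
  standard price of signal exclusion.
* **Multi-transcriptome statistic** (`meta_combine()`):
  \(\chi^2_{(1)} = (\sum_n t_n / \sqrt N)^2\) over the N tissues in which
  the pair was tested. The null hypothesis is no association in *any*
  tissue, and cross-tissue independence of t under the null is assumed —
  an assumption the shared-animal blood/milk design strictly violates. An
  effective-N correction (dividing by the mean of the cross-tissue t
  correlation matrix) is available behind `effective_n = TRUE`, default
  off to match the reference design.

The validation design (`run_validation()`) restricts to pairs with
p < 0.05 in each of three tissues, combines them, and cross-tabulates
meta-significance (p < 1e-5) against significance in a held-out tissue at
p < 0.05, testing the overlap with Fisher's exact test. Overlap tests
throughout (`fisher_overlap()`) are one-sided in the enrichment direction,
with the background defined as the union of analysed SNPs (configurable).
A greedy ±1 Mb lead-SNP clumping utility is provided but is a convenience,
not a validated locus definition.

## The synthetic-data generator

Every stage is validated against `sim_config()` + `simulate_genotypes()` +
`simulate_counts()`, which plant a recoverable ground truth
(`sim_truth()`):

* **Genotypes.** Two haplotypes per individual per gene window; each
  allele copies its left neighbour with probability `ld_decay`, otherwise
  it is redrawn, giving first-order autoregressive LD (adjacent-SNP
  correlation `ld_decay`, decaying geometrically with SNP distance) and
  Hardy–Weinberg genotypes within breed. All SNPs of a window share one
  allele frequency, drawn per window from `maf_range` — this makes the
  copy mechanism's correlation target exact while MAF still varies across
  windows. Breed structure enters as an allele-frequency offset.
* **Counts.** Latent gene log2 expression is `beta * dosage + a + e` with
  the local polygenic value `a = Z u` built from the window's standardised
  dosages, `var(a) = h2_local` (default 0.5) and per-SNP effects `u`
  correlated `cross_tissue_rg` across tissues. Planting the correlation at
  the SNP-effect level (rather than as iid per-individual values) is what
  makes the GRM-structured REML estimand *exactly* `cross_tissue_rg`;
  per-individual bivariate noise would be unidentifiable against the
  residual covariance whenever samples are shared. Counts are negative
  binomial with dispersion 0.1 — a standard bulk RNA-seq figure; no count
  distribution is prescribed by the design being emulated.
* **Splicing.** Exon usage partitions each gene's reads (baseline 0.35 at
  the target exon, the remainder split evenly), so exon library size
  tracks gene library size and the inclusion ratio is anchored near its
  usage value. sQTL genes move the target exon along a logistic-in-dosage
  curve whose slope is solved (by `uniroot`) so the dosage-2 minus
  dosage-0 inclusion difference equals `usage_shift` exactly — the planted
  value is the recoverable value. The junction cluster reweights so the
  intron adjacent to the target exon gains share as the exon is excluded.
  At most one causal SNP per gene is planted; multi-causal architectures
  are out of scope for fixtures.
* **GWAS summaries.** Per-SNP effects drawn around planted truths with
  cohort-specific standard errors (default bull 1, cow 2) emulate
  sex-separated cohorts with different phenotypic error.

What the generator does **not** emulate: read-level noise, mapping or
coverage bias, RNA degradation, genotype imputation error, linkage between
windows, and multi-causal cis architecture. Passing tests therefore show
the estimators are correct under their own assumptions at realistic sizes
— not that real-data counts (which depend on those unmodelled features)
would be reproduced.

## Study conditions used by the checks

The simulation studies (`study_*` functions, also run by
`scripts/acceptance.R`) use: 50 replicates of n = 200 for sQTL recovery at
usage shift 0.3 with four effect-free genes per replicate; 50 replicates
of n = 300 shared individuals, h² = 0.5, for genetic-correlation recovery
at true r ∈ {0, 0.8}; 10,000 null pairs for meta calibration; and 1000
null features on 20 animals × 3 tissues for the mixed-model type-I error.
These sizes give Monte-Carlo standard errors comfortably inside the stated
tolerances (e.g. ±0.04 on a recovery proportion of 0.9) while keeping a
full run in minutes on one CPU.

## Known limitations

* The sQTL/eeQTL stringency asymmetry noted above is reproduced, not
  resolved.
* The \(\chi^2_{(1)}\) meta-statistic's independence assumption is only
  approximate for shared-animal tissue pairs; the effective-N flag exists
  but is off by default.
* Storey's pi0 smoother needs a few hundred p-values to be stable; below
  100 the implementation falls back to pi0 = 1 (Benjamini–Hochberg).
* Disjoint-sample designs identify the genetic correlation only through
  cross-cohort relatedness, which is weak for unrelated simulated
  individuals; estimates there are reported with correspondingly large
  standard errors.
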