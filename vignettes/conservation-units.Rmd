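---
title: "Delineating conservation units from landscape genomic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating conservation units from landscape genomic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cudelim)
```

## The problem

Conservation units (CUs) for harvested anadromous fishes are delineated from
two lines of evidence: demographic independence (hierarchical population
structure and restricted gene flow) and adaptive differentiation (loci whose
allele frequencies track the environment rather than shared history). In
post-glacial species both signals are entangled with colonization: two
long-diverged glacial lineages meeting in a secondary-contact cline produce
an ancestry gradient that dominates genetic distances and is itself
correlated with latitude and environment. `cudelim` implements the full
analysis chain needed to separate these signals from population
allele-frequency tables: genetic distance matrices, structure summaries,
a Mantel-based decomposition of isolation by distance (IBD), environment
(IBE) and colonization (IBC), per-SNP selection scans and gene-environment
association (GEA), gene-level aggregation, and multi-method consensus.

Because real low-coverage whole-genome datasets are far beyond desk scale,
the package ships a synthetic-data generator that reproduces the statistical
structure those analyses assume, together with ground-truth tables, so every
stage can be validated end to end.

## The synthetic landscape generator

`sim_config()` / `simulate_dataset()` emulate:

* **A coastline of populations.** `n_pops` sites are placed along a gently
  meandering 2-D polyline; marine distance is the along-coast path length,
  an exact metric. Coordinates are in arbitrary coastline units (default
  inter-site spacing averages 1 unit).
* **A two-lineage admixture cline.** Site ancestry `q` follows
  `plogis(cline_steepness * (s - s_mid))` in along-coast position `s`, plus
  truncated Gaussian noise (sd 0.03). The default `cline_steepness = 0.3`
  over a ~30-unit coastline spans q from about 0.01 to 0.99, i.e. nearly
  pure lineages at the two ends with a broad admixed middle. Sites with
  q < 0.5 are flagged "north", the rest "south".
* **Lineage divergence and local drift.** Ancestral frequencies are
  Uniform(0.05, 0.95); the two lineage frequencies follow the
  Balding-Nichols Beta model with `f_div = 0.3`; each site's base frequency
  mixes lineages by its q; local drift applies a second Balding-Nichols
  draw with `f_drift = 0.05`. These two F values were chosen as typical of
  deep inter-lineage divergence versus within-lineage river-scale drift in
  anadromous salmonids, and the Beta parameterization has an analytically
  checkable FST expectation (tested against a brute-force Monte-Carlo
  oracle).
* **Environment partially confounded with ancestry.** `n_env_vars = 11`
  standardized environmental variables are Gaussian processes on the
  coastline (exponential covariance, range = coastline/5). Variable 1 is
  constructed to have sample correlation exactly `env_ancestry_corr`
  (default 0.3) with q — the "partially confounded" regime that makes GEA
  hard and motivates the ancestry-corrected analyses.
* **A minority of adaptive genes.** Of `n_genes = 1000` annotated gene
  intervals, `n_adaptive_genes = 20` carry environment-coupled SNPs: before
  drift, their logit frequencies are shifted by `beta_env * sign_g * env1_i`
  with `beta_env = 1` (an e-fold odds shift per environmental standard
  deviation — a strong adaptive cline) and a random per-gene sign.
* **Low-coverage-style missingness.** Per SNP and site, the number of
  individuals informing the frequency is a binomial thinning of
  `n_ind_per_pop = 30` at rate `1 - missing_rate` (default 0.25); genotype
  dosages are independently masked at the same rate.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (frequencies are conditionally independent given gene membership and
q), genotype-likelihood uncertainty (dosages are drawn exactly), sequencing
error, and spatially heterogeneous sampling. Passing tests therefore
demonstrate correctness and calibration of the statistical machinery, not
robustness to LD-induced pseudo-replication within genes — on real data the
gene-level aggregation must absorb that, which is precisely why its weights
and rank basis matter.

## Distances

* **FST** uses the Hudson estimator in ratio-of-averages form with the
  finite-sample correction
  `N = (p_a - p_b)^2 - p_a(1-p_a)/(n_a-1) - p_b(1-p_b)/(n_b-1)`,
  `D = p_a(1-p_b) + p_b(1-p_a)`, `FST = sum(N)/sum(D)`. It is unbiased from
  allele frequencies, robust to rare SNPs, and has a trivially codeable
  per-SNP oracle. SNPs need n >= 2 allele copies in both populations;
  the global folded MAF filter (default strict > 0.01) is applied as a
  dataset-level mask, not per pair.
* **AFD** is the mean absolute per-SNP frequency difference — bounded in
  [0, 1] and nearly linear in divergence time at these scales.
* **p-distance** between individuals is the mean dosage difference /2 over
  co-observed SNPs, optionally scaled by (number of SNPs)/(genome length)
  to express it per genomic site.
* **Environmental distance** standardizes the site x variable table, runs a
  PCA and takes Euclidean distance on the smallest set of leading axes
  reaching 92% cumulative variance (default), or an explicit axis count.
* **BIONJ** trees are built by an in-package double-precision
  implementation of variance-weighted neighbor joining; additive matrices
  are reproduced exactly (path lengths to ~1e-15), negative branch lengths
  are kept so additivity checks stay exact, and agglomeration ties break on
  the lexicographically smallest label pair so topology does not depend on
  input order.

## Structure summaries

PCA uses Patterson standardization `sqrt(2p(1-p))` for genotypes and plain
centering for frequency matrices; axis signs are fixed by the
largest-magnitude loading. LD is the squared Pearson correlation of dosages
over co-observed individuals within 500 kb; pruning builds the graph of
pairs within 200 kb with r^2 > 0.1 and repeatedly deletes the
highest-degree node (ties: larger incident r^2 sum, then larger position),
asserting afterwards that no offending pair survives. Replicate admixture
runs are grouped into modes by a label-switching-invariant similarity
`1 - (1/2N) min_P sum|Q - Q'P|` with linking threshold 0.85; the major mode
is averaged after aligning members to its highest-likelihood run, making
the result invariant to run order and column permutation. `evanno_delta_k()`
computes the second-order rate of change of the mean log-likelihood scaled
by its standard deviation, undefined at the end points.

## The isolation decomposition

Mantel tests use the Pearson correlation of lower triangles, one-sided
(positive) alternatives — isolation hypotheses are directional — and the
add-one permutation convention `p = (1 + b)/(1 + B)` so p is never 0. The
partial test correlates residuals after regressing both triangles on the
covariate triangle, and permutes the *first matrix's* row/column order
jointly, recomputing its residuals per permutation; this preserves the
covariate's structure. If the covariate explains one side exactly, the
partial r is reported as 0 with p = 1.

The residual-substitution step regresses genetic distance on ancestry
distance plus pair-category terms (north-north / south-south /
north-south). The default model uses category intercepts and a common
ancestry slope; `interaction = TRUE` adds category-specific slopes. On the
synthetic landscape the AFD-ancestry relation has category-dependent
slopes by construction — northern pairs sit on the flat drift floor while
mixed pairs lie on the steep lineage-contrast limb — so the package's
validation experiments use the interaction variant; with the intercept-only
model the leftover curvature correlates with marine distance (which tracks
ancestry distance almost perfectly along a cline) and masks both the IBD
null and the IBE signal. On data where the relation is linear the two
variants coincide.

In those validation experiments the marine (IBD) test controls the known
driver-variable distance; the environment is spatially autocorrelated, so
controlling a weaker environmental summary would let true environmental
signal leak into the marine test and be mistaken for type-I error.

## Scans and gene-environment association

* **pcadapt-style scan.** Genotypes are MAF-filtered (> 0.05),
  mean-imputed, Patterson-standardized; per-SNP z-scores are the
  regressions on k principal components scaled by the residual sd; the
  z cloud's robust covariance comes from a one-step orthogonalized
  Gnanadesikan-Kettenring estimator (median/MAD scales) implemented
  in-package; Mahalanobis distances are rescaled by the genomic inflation
  factor `lambda = median(D^2)/median(chi^2_k)` and converted to upper-tail
  chi-squared p-values. The degrees of freedom default to k but are
  exposed separately (`df`), since fixed-PC analyses are sometimes reported
  with k-1 degrees of freedom.
* **RDA / pRDA.** The response is the site x SNP frequency matrix, column
  centered (no Hellinger transform — frequencies are already bounded
  compositional summaries); predictors are standardized; the partial
  variant residualizes both sides on the covariate. R^2 is SS_fit/SS_total
  with the Ezekiel adjustment `1 - (1-R^2)(n-1)/(n-m-1)`. Axis significance
  uses a pseudo-F (axis eigenvalue over residual mean square) under free
  row permutation of the (residualized) response, retaining axes
  sequentially while p < 0.05. Permutations operate on the n x n response
  cross-product, so they cost O(n^2 rank) regardless of SNP count.
  Predictor selection is VIF pruning (drop the largest until all < 10;
  ties drop the later column) followed by backward selection on drop-one
  marginal pseudo-F permutation p-values (stay threshold 0.1).
* **Variance partitioning** computes the Ezekiel-adjusted R^2 of the seven
  non-empty unions of three predictor sets (environment, ancestry,
  geography) and applies inclusion-exclusion; the seven signed fractions
  sum to the full-model adjusted R^2 by construction and the identity is
  asserted to 1e-10. Fractions can be slightly negative, as with any
  adjusted-R^2 partition.
* **Univariate GEA** is the absolute Spearman correlation between
  population frequencies and each variable — a deliberately simple,
  rank-based analog of Bayes-factor GEA statistics, labeled `bf_analog`;
  the consensus machinery accepts any external per-SNP statistic table in
  the same `scan_stats()` format.
* **Allele-count export** multiplies frequencies by allele-sample counts
  and rounds half-to-even, so minor + major may differ from n by 1.

## Gene-level aggregation and consensus

SNPs are assigned to genes by half-open interval arithmetic (BED 0-based
[start, end); a 1-based SNP position P belongs iff start <= P-1 < end);
genes with fewer than 5 assigned SNPs are dropped from both testing and the
background. Each per-SNP statistic is rank-converted to empirical p-values
(already-p-valued inputs are used directly), mapped to z-scores, and
combined per gene as `Z = sum(w_i z_i)/sqrt(sum(w_i^2))` with
heterozygosity weights `w_i = p(1-p)` from the global MAF — the
denominator is what corrects for the number of SNPs per gene. The gene
p-value defaults to the upper normal tail of Z; an empirical rank-across-
genes mode is provided for datasets whose Z null is not well approximated
as normal. Because only ranks enter, the aggregation is invariant to any
strictly monotone transform of a "higher is more extreme" statistic.

Top candidates use a strict p < 0.001 cut. Pairwise overlap percentages
use the union of the two sets as denominator (other conventions, e.g. the
smaller set, give slightly different percentages; the choice is stated in
the output). The consensus list contains genes flagged by at least two
methods. Region enrichment is a 2x2 Pearson chi-squared without continuity
correction (immaterial at genome-scale backgrounds; a flag restores it),
BH-corrected across the whole (method, region-class) family; QTL proximity
expands gene intervals by 100 kb in half-open arithmetic; term enrichment
is a one-sided hypergeometric with BH correction.

## Numerical conventions and degenerate inputs

Frequencies are clamped to [1e-6, 1 - 1e-6] in the generator; all-missing
SNP/population cells carry NA frequency with n = 0 and are excluded by the
n >= 2 filters; permutation p-values are never 0; constant environmental
variables are dropped (distance) or reported as NA (per-variable tests)
with warnings; a degenerate robust covariance falls back to the classical
estimate with a warning; rank ties use average ranks throughout.

## Validation problem sizes

The test suite validates calibration and recovery at deliberately chosen
sizes: Mantel type-I over 1000 null replicates of 30 sites (199
permutations, so the rejection rule at alpha = 0.05 is exact); scan
calibration over 100 simulated datasets of 30 populations x 2000 SNPs
(k = 15); the isolation decomposition over 200 replicates at the full
default conditions (30 populations, 20k SNPs, 1000 genes, 20 adaptive
genes); gene-level recovery, ranking AUC and consensus on single default
datasets. Oracles are exhaustive enumeration (5-label Mantel,
hypergeometric tail), closed forms (three-taxon trees, WZA toy), and
brute-force recodings (Hudson FST, BH step-up, least-squares RDA), plus
cross-checks against `vegan` (Mantel, RDA) and `ape` (BIONJ) where those
implement the same computation.

## Known limitations

Admixture inference itself (the EM that produces Q matrices) is out of
scope — the package post-processes replicate Q matrices from any source.
Bayesian covariate models (XtX / Bayes factors) are not reimplemented; the
`bf_analog` statistic is a stand-in with the same interface. Genotype
likelihoods are not modeled: all individual-level computations consume
dosages. Effective-migration surfaces and GIS environmental extraction are
outside the package. The generator's independence of SNPs given gene
membership means gene-level p-values on real, LD-rich data will be more
correlated than the synthetic calibration suggests.
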