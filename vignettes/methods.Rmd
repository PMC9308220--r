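---
title: "Models and methods behind pinegp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pinegp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pinegp` implements the quantitative-genomic toolchain used for multi-site,
multi-trait open-pollinated (OP) conifer progeny trials: genomic
relationship matrices from SNP dosages, single- and multi-trait GBLUP mixed
models fitted by REML, GWAS through back-solved SNP effects, a family of
Bayesian whole-genome regression and kernel prediction engines with
trait-assisted cross-validation, and a seeded simulator that provides
ground-truth data for every stage. This vignette describes the models, the
numerical choices, and what the synthetic test bed does and does not
establish.

## The mixed models

The single-trait, single-site individual-tree model is

$$y = X\beta + Z_d d + Z_a a + e$$

with genetic-group (provenance) means as the only fixed effects, random
design effects $d$ for replication and set-within-replication, additive
genetic effects $a \sim N(0, G\sigma^2_a)$ and residuals
$e \sim N(0, I\sigma^2_e)$. Plot effects are not modeled: in the trial
design emulated here a single tree is sampled per 4-tree row plot, so plot
and tree are confounded. The genomic relationship matrix is

$$G = \frac{WW'}{2\sum_i p_i(1-p_i)}, \qquad W = M - P,$$

where $M$ holds 0/1/2 alternative-allele dosages and $P$ broadcasts twice
the in-sample allele frequencies $p_i$. Because the columns of $W$ are
centered on in-sample frequencies, $\mathbf{1}'W = 0$ and the raw $G$ is
always singular; `compute_grm()` therefore blends
$G \leftarrow (1-\alpha)G + \alpha I$ with $\alpha = 0.01$ by default,
which guarantees a positive-definite, invertible matrix without requiring
a pedigree relationship matrix. When an unblended $G$ is supplied (as in
some equivalence checks), the REML machinery restricts the additive effect
to the positive eigenspace of $G$, which is the natural pseudo-inverse
treatment of the centering constraint.

The multi-trait model treats either several traits measured on the same
trees or one trait's records at different sites as distinct responses:

$$y^* = X\beta + Z_a a + e, \qquad
\mathrm{Var}(a) = \Sigma_a \otimes G, \quad
\mathrm{Var}(e) = \Sigma_e \otimes I .$$

It is fitted on design-adjusted, standardized phenotypes, so the design
random effects drop out and the genetic groups remain the only fixed
effects. In site-split mode every tree carries one record at its own site
and the cross-site residual covariances are structurally zero (sites are
assessed separately); the cross-site genetic correlation from
$\Sigma_a$ then indexes genotype-by-environment interaction.

Heritability and genetic correlations are estimated as
$\hat h^2 = \hat\sigma^2_a / (\hat\sigma^2_a + \hat\sigma^2_e)$ and
$\hat r_a = \hat\sigma_{a_{ij}} / \sqrt{\hat\sigma^2_{a_{ii}}
\hat\sigma^2_{a_{jj}}}$. Note that $\hat h^2$ deliberately excludes the
design variances, matching the estimator conventional for adjusted
progeny-trial data.

### REML algorithm and numerical choices

Variance components are estimated by EM-REML iterated to convergence
(change of every component below `1e-6` of the phenotypic variance —
scaling by the phenotypic variance rather than by each component keeps
boundary components, whose EM decay is slow, from stalling the stop rule —
at most 2000 single-trait (500 multi-trait) iterations;
components are floored at `1e-8` times the phenotypic variance, which is
where null-signal fits park their additive variance), followed by one
average-information (AI) evaluation whose inverse supplies approximate
standard errors; delta-method SEs for $\hat h^2$ and $\hat r_a$ derive
from that matrix. EM was chosen for its guaranteed monotone REML
likelihood — the fitter records the likelihood path and the test suite
asserts monotonicity — and the single AI step supplies the curvature
information EM lacks. The closed-form SE formulas are not part of the
estimator itself; treating the AI inverse as the asymptotic covariance is
our interpretation of standard practice.

Two implementation paths give the same answer (this equality is itself a
test):

* **Canonical path** (complete records, shared fixed design): each EM
  iteration simultaneously diagonalizes $(\Sigma_a, \Sigma_e)$, after
  which the multi-trait problem decouples into $t$ univariate problems in
  the eigenbasis of $G$, each solvable in $O(n)$ given the one-time
  eigendecomposition. This is exact, not an approximation.
* **Dense path** (missing trait cells, site-split layouts): per-record
  incidence on the full mixed-model equations with the complete
  $C^{-1}$ formed at every iteration. It is intended for desk-scale problems
  (a few hundred trees in site-split mode). For scattered missing cells
  the residual EM update uses the pairwise-observed form; it is exact for
  the two record patterns the models actually use (complete rows, and
  disjoint site-split rows), and is a documented approximation in between.

Prediction-error (co)variances of the breeding values are extracted from
the mixed-model-equation inverse — in structured (eigenbasis + low-rank)
form on the fast path, densely on the dense path — with no approximation.

## GWAS by back-solving

SNP effects are obtained as a linear transformation of the fitted genomic
breeding values:

$$\hat g = \frac{1}{2\sum_i p_i(1-p_i)} W'G^{-1}\hat a, \qquad
\mathrm{Var}(\hat g) = s^2\, W'G^{-1}\,\mathrm{Var}(\hat a)\,G^{-1}W,$$

with $\mathrm{Var}(\hat a) = \sigma^2_a G - \mathrm{PEV}$ taken from the
MME inverse, and each SNP is assigned the two-sided normal p-value
$p_k = 2(1 - \Phi(\hat g_k / \mathrm{sd}(\hat g_k)))$. At fixed variance
components this reproduces SNP-BLUP (ridge) effects and Wald p-values
exactly on small instances, which the test suite checks against dense
oracles. The GWAS models drop genetic groups and design effects (they run
intercept-only on adjusted phenotypes, appropriate when provenance
structure explains a negligible share of marker variation, as in the data
the simulator emulates); family-wise error is controlled by Bonferroni
division of $\alpha$ by the number of SNPs, compared on the p-scale rather
than a rounded $-\log_{10}$ scale, with the nominal 0.05 flag also
reported. For the multi-trait scan, the transformation is applied per
trait using that trait's sub-vector of $\hat a$ and the corresponding
block of the multi-trait MME inverse.

## Prediction engines

Five single-trait engines operate on adjusted, standardized phenotypes:

* **BRR** — Gibbs sampler with i.i.d. normal marker effects;
* **BayesC** — spike-slab prior with sampled inclusion probability
  ($\pi \sim \mathrm{Beta}(1, 99)$, prior mean 0.01, sampled rather than
  fixed);
* **BLasso** — double-exponential prior via the normal/exponential scale
  mixture, $\lambda^2$ under a gamma hyperprior centred so the implied
  marker-variance matches a half/half variance split;
* **GBLUP** — kernel regression with the linear $G$ kernel;
* **RKHS** — kernel regression with the Gaussian kernel
  $K = \exp(-h\,d^2)$ on squared Euclidean marker distances.

Variance priors are scaled-inverse-$\chi^2$ with df 5 and scale set so the
prior mode splits the phenotypic variance half/half between signal and
residual; these are weakly informative defaults in line with common
whole-genome-regression practice and are config-exposed. The squared
distances of the Gaussian kernel are divided by their off-diagonal mean,
making $h$ dimensionless so that a bandwidth grid such as
$\{0.1, 0.25, 0.5, 1, 2.5\}$ — and the commonly selected $h = 0.5$ —
transfers across marker panels; a flag disables the normalization.
`select_bandwidth()` picks $h$ by cross-validated predictive ability with
ties going to the smallest candidate. With the linear $G$ kernel, kernel
regression is the GBLUP model, and the package treats that equivalence as
a correctness test (prediction correlation above 0.99 between the two
routes).

The multi-trait engines (MT-GBLUP, MT-RKHS) share one Gibbs sampler with
matrix-normal genetic values (row covariance $K$, unstructured trait
covariance under an inverse-Wishart prior with df $t+2$ and scale half the
trait variances) and i.i.d. multivariate-normal residual rows. Missing
cells are sampled by data augmentation, which implements trait-assisted
prediction: a validation tree keeps its non-focal phenotypes and they
inform its genetic value through the sampled trait covariances. Each
iteration simultaneously diagonalizes the two trait covariances so all
genetic values are drawn in vectorized form.

Chain defaults are desk-scale (3,000 iterations, 500 burn-in, thin 5),
chosen so that full test runs complete on a single CPU; the long
single-chain settings typical of published analyses (20,000/2,000/100 for
single-trait, 200,000/1,000/100 for multi-trait) are available as
`chain_config(preset = "paper_st")` / `"paper_mt"`. All samplers draw
exclusively from R's RNG, so every run is bit-reproducible from its seed.
Independent chains are run per cross-validation fold (no warm starts), so
folds are exchangeable.

## Cross-validation and method comparison

`run_cv()` performs replicated k-fold cross-validation (10 folds and 5
replicates by convention; smaller designs for desk runs), stratified by
site so folds are balanced across trials. Fold assignment is
individual-level: relatives may span training and validation, which
mirrors how such trials are usually evaluated; a stricter family-aware
split can be had by passing the family as the stratification factor and
k-fold at the family level, but that is not the default. Recorded per
trait × model × fold × replicate:

* **predictive ability** — Pearson correlation between predicted genetic
  values and adjusted phenotypes of validation trees;
* **accuracy** — predictive ability divided by $\sqrt{\hat h^2}$, with
  $\hat h^2$ taken once from the full-data MT-GBLUP REML fit;
* **bias** — OLS slope of observed adjusted phenotype on prediction
  (1 = unbiased, smaller = inflated).

`compare_methods()` averages folds within replicates and fits the
fixed-effects model `value ~ method + replicate` per trait and pooled,
followed by Tukey HSD at $\alpha = 0.05$ and a compact letter display.
Treating replicates as blocks and applying Tukey to replicate-level means
is the conventional reading of a "method + replication" comparison; fold
is not a factor because folds are exchangeable within a replicate.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults describe a four-site OP progeny-trial series of
the lodgepole pine type: 40 OP families from five provenances, about ten
offspring per family per site (~1,600 trees), a set-in-reps design with
five replications (seven sets per replication at desk scale), 13
correlated traits spanning growth, wood quality, pest scores, a drought
indicator and monoterpene concentrations, per-site heritabilities spanning
0.0–0.8, mostly strong cross-site genetic correlations, four-category
ordinal pest ratings, and 5,000 SNPs with founder MAF down to 0.01 and
missing calls at 15%. Where the emulated trial series does not pin down a
value we made one fixed, documented choice: replication and
set-within-replication variances default to 5% of phenotypic variance
each, provenance means to 2% (deliberately small, consistent with
negligible provenance structure), and the desk marker panel is 5,000 SNPs
rather than a GBS-scale 25,000 to keep eigendecompositions affordable —
the GRM's statistical behaviour at these scales is equivalent for testing
purposes.

Breeding values carry the (trait × site) covariance formed by the
Kronecker combination of the trait and cross-site correlation matrices
scaled by $\sqrt{h^2}$ (eigenvalue-clipped at `1e-8` if composition ever
leaves the PSD cone). In causal mode, effects load on 300 shared QTL
(pleiotropy through correlated per-QTL effect vectors); in infinitesimal
mode they descend through the pedigree by Mendelian sampling. Realized
additive variances are rescaled to the exact targets so stated
heritabilities are true in-population values. Pollen parents are drawn
uniformly from same-provenance founders — the OP half-sib assumption with
hidden relatedness, since no paternity information exists in such trials.

Deliberately not modeled: linkage maps or LD beyond family
co-inheritance, the informative missingness of genotyping-by-sequencing
(missingness here is completely at random), selection across generations,
and spatial field trends. Passing tests on this generator therefore
establish internal correctness (estimators recover known truth;
algebraic equivalences hold) — they do not establish robustness to
LD structure, informative missingness, or spatial autocorrelation in real
trial data.

## Degenerate inputs and tie-breaking

Monomorphic-only panels, all-missing SNP columns, constant traits,
single-category ordinal vectors, zero prediction variance in the bias
slope, empty bandwidth grids and sub-minimal validation folds (fewer than
3 phenotyped trees) are all rejected with explicit errors; covariance
estimates that leave the PSD cone are projected back by eigenvalue
clipping and flagged. Bandwidth ties take the smallest `h`; Bonferroni
significance is decided on the p-scale.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run, by choice, at desk
scale on one CPU: oracle checks on 30-tree × 50-SNP fixtures; parameter
recovery at n = 1000 (heritability) and n = 800 (genetic correlation);
GWAS calibration on a 300-tree × 2000-SNP null population; directional
multi-trait comparisons on ten seeded replicates of small two-trait
populations; and one end-to-end pipeline run on the full ~1,600-tree ×
5,000-SNP, 13-trait fixture with shortened Gibbs chains.
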