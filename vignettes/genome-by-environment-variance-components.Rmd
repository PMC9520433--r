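---
title: "Decomposing trait variance into genetic, exposure and genome-by-exposure components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing trait variance into genetic, exposure and genome-by-exposure components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`gxevc` estimates how much of the variation in a quantitative or binary
trait is attributable to common genetic variation, to a measured
environmental exposure (the motivating case is self-reported trauma), and
to their interaction. The working model is the four-component mixed linear
model

$$y = X\beta + g + e + g{\times}e + \varepsilon,$$

where $g \sim N(0, \mathbf{G}\sigma^2_G)$ with $\mathbf{G}$ the genomic
relationship matrix (GRM) built from standardized genotype
cross-products, $e \sim N(0, \mathbf{E}\sigma^2_E)$ with $\mathbf{E}$ an
environmental relationship matrix (ERM) built analogously from
standardized exposure principal components, and
$g{\times}e \sim N(0, (\mathbf{G}\circ\mathbf{E})\sigma^2_{G \times E})$ with
$\circ$ the Hadamard (cell-by-cell) product. By the Schur product theorem
the interaction kernel is positive semidefinite whenever its factors are.
Fixed covariates are an age-like variable, sex (in sex-joint analyses),
a genotyping-batch indicator and the leading principal components of the
full-sample GRM (15 by default) to guard against population
stratification.

Nested submodels — genetics only ({G}, model 1), exposure only ({E},
model 2), both main effects ({G, E}, model 3) and the full interaction
model ({G, E, GxE}, model 4) — are compared by likelihood-ratio tests.
Because a variance component is tested on the boundary of its parameter
space, the null reference for one extra component is the 50:50 mixture of
a point mass at zero and $\chi^2_1$; `lrt()` generalizes this to the
binomial mixture for several components.

## REML estimation

`fit_reml()` maximizes the restricted likelihood of
$V = \sum_i \sigma^2_i K_i + \sigma^2_\varepsilon I$ with a small number
of expectation-maximization warm-up iterations (3 by default — EM is slow
but monotone and tolerant of poor starting values) followed by
average-information (AI) updates with step-halving. Starting values split
the phenotypic variance equally across components. Components driven
negative are clamped at zero and the AI system re-solved over the free
components; a clamped component whose score turns positive re-enters.
Convergence requires a relative log-likelihood change below `1e-8` and a
maximum parameter change below `1e-6` of the phenotypic variance — tight
enough that an independent derivative-free maximization of the same
restricted likelihood agrees to `1e-6` at $n = 60$ within float64
headroom. Standard errors come from the inverse AI matrix at the optimum
and proportion SEs from the first-order delta method; a parametric
bootstrap agrees with the delta-method SEs to well within 25% at
$n = 400$.

Each AI iteration needs one $n \times n$ Cholesky inversion; all traces
use $\mathrm{tr}(PK) = \langle V^{-1}, K\rangle$ minus a low-rank
correction, so the per-iteration cost is a single $O(n^3)$ factorization
and fits at $n = 2000$ take seconds. This keeps the whole analysis in
plain R on one core.

Binary traits are analyzed on the observed 0/1 scale and the resulting
variance proportions transformed to the liability scale with the
threshold-model conversion
$h^2_{lia} = h^2_{obs}\,K^2(1-K)^2 / (z^2 P(1-P))$, where $K$ is the
population prevalence, $P$ the sample case proportion (defaulting to
$P = K$, the population-sample case; both conventions are supported
because published workflows vary) and $z$ the standard normal density at
the $(1-K)$ quantile. At $K = P = 0.5$ the factor reduces to $\pi/2$.
The conversion rescales estimates only: likelihoods, tests and their
significance pattern are unchanged across prevalences, which is exactly
what the prevalence sensitivity analysis (`sensitivity_prevalence()`)
verifies.

## Exposure representation

Questionnaire items are summarized by `compute_trauma_pcs()`:
standardization, then eigendecomposition of the item correlation matrix
(correlation, not covariance, because items sit on heterogeneous scales).
Missing responses are mean-imputed per item. Category subsets (childhood
/ adult / catastrophic) use the same machinery on the labelled item
subset. The ERM weights all retained PCs equally after standardization,
making it the Mahalanobis-whitened cross-product of the items; a PC1-only
variant is available because a single leading eigenvector is a common
reduced representation. Eigenvector signs always follow the
largest-magnitude-loading-positive convention so results are identical
across linear-algebra backends.

Because exposures can be heritable, gene-environment correlation can leak
genetic variance into $\sigma^2_E$ and bias $\sigma^2_G$. The designed
control is `precorrect_pcs()`: each exposure PC is fit under model 1
(GRM as the single kernel) and replaced by
$y - X\hat\beta - \widehat{\mathrm{BLUP}}(g)$, i.e. the genetic random
effect is removed in the mixed-model sense rather than by ordinary
regression on matrix columns. The package's paired simulations show the
precorrected and uncorrected component estimates agree within sampling
error at moderate gene-environment correlation, while the residualized
PCs refit under model 1 carry essentially zero heritability.

## The synthetic cohort generator

No suitable individual-level dataset can be redistributed, so the
generator is a first-class module reproducing the statistical structure
the analysis assumes, at configurable scale:

* genotypes: $m$ biallelic SNPs in Hardy-Weinberg equilibrium, MAF
  uniform on a configurable range (default 0.05–0.5); optional full-sib
  pairs created by gene dropping through simulated parents, so realized
  relatedness (mean GRM entry 0.5) is genuine rather than a perturbed
  matrix;
* a latent exposure with SNP heritability `trauma_h2` (default 0.17, the
  benchmark scale for full trauma; 0.15 is used for childhood-scale
  scenarios), its genetic part a weighted sum of causal-SNP genotypes;
  the non-genetic part is orthogonalized so realized variance fractions
  are exact;
* binary questionnaire items as thresholded noisy copies of the latent
  factor (loading $\sqrt{0.5}$), endorsement rates spread over 0.15–0.5 —
  real item response scales are not public, so 2-point items are the
  simplest faithful stand-in and are flagged as synthetic;
* a phenotype with exact realized variance fractions
  (`var_g`, `var_e`, `var_gxe`, `var_resid`, default 0.16/0.18/0.20/0.46,
  the benchmark decomposition), genetic correlation `rg_trauma_pheno`
  with the exposure through shared causal variants, optional
  liability-threshold dichotomization at an exact empirical-quantile
  prevalence, five near-equal random clusters, sex labels at 52% female,
  and a male:female interaction-variance ratio (`sex_gxe_ratio`, 5 in the
  sex-contrast benchmark).

Two exposure modes matter for interpretation. In the default
`e_mode = "latent"`, the environmental effect *is* the latent factor —
the scientifically literal reading, but the resulting rank-1 exposure
kernel leaves $\sigma^2_E$ weakly identified (its sampling error barely
shrinks with $n$). In `e_mode = "kernel"`, `e` is drawn multivariate
normal from the item-PC ERM itself, giving the well-specified regime in
which the kernels used for fitting are exactly the generative ones. The
pipeline's simulation mode and the recovery benchmarks use kernel mode;
latent mode is kept for studying misspecification. Recovery benchmarks
also set `rg_trauma_pheno = 0`: with genetic correlation present, part of
g's covariance runs through the causal-SNP direction that also spans the
exposure kernel, and the resulting ~0.02–0.03 transfer from $\sigma^2_G$
to the residual is the genuine gene-environment-correlation confound —
studied via the precorrection comparison, not mixed into parameter
recovery.

The interaction draw eigendecomposes $\mathbf{G}\circ\mathbf{E}$ and
clips negative eigenvalues at zero (they are floating-point noise for
genuine Hadamard kernels; the clipped mass is checked against a `1e-8`
relative tolerance and the draw aborts with a diagnostic beyond it).

What passing tests show — and what they do not: the generator draws
exactly from the model the estimator fits, so recovery results certify
the estimation machinery, not robustness to real-data features such as
linkage disequilibrium, item-specific reporting biases, ascertainment, or
cryptic structure beyond what the GRM captures.

## Haseman-Elston regression

`he_univariate()` regresses pairwise products of the
covariate-residualized, unit-variance trait on off-diagonal GRM entries
over all $j<k$ pairs (diagonals excluded, the standard convention); the
slope is the SNP heritability on the standardized observed scale.
`he_bivariate()` regresses symmetrized cross-products for the genetic
covariance and forms $r_g = \mathrm{cov}_g/\sqrt{h^2_1 h^2_2}$, defined
only when both heritabilities are positive (an explicit status is
returned otherwise; $r_g$ clipping into $[-1,1]$ is optional and
recorded). Standard errors use the leave-one-individual-out jackknife;
all pair sums have $O(n)$ per-individual downdates, so exact delete-1
costs $O(n^2)$ overall and is the default up to $n = 5000$, with a
delete-block mode (100 blocks) beyond. The jackknife resamples the HE
regression stage with the covariate residualization held fixed, matching
common practice for these moment estimators. When averaging $r_g$ across
simulation replicates the clipping is disabled, since truncating at 1
would bias the mean of a noisy ratio estimator.

## Meta-analysis across clusters

Large cohorts make a single joint fit intractable, so the design splits
the sample into clusters (geographic in the motivating study; random
labels in simulation), analyzes each independently, and pools estimates
by inverse-variance weighting: fixed-effect, DerSimonian-Laird, and a
scalar-REML random-effects variant, with Cochran's Q, $\tau^2$ and
$I^2$ reported. The pooling method is a required configuration key with
no silent default, because fixed- versus random-effects pooling is a
substantive choice the analyst must own; all three are cheap enough to
report side by side.

## Pipeline and reproducibility

`run_study()` executes the full grid — cluster × sex stratum × trauma
category × model — building all kernels per cluster (GRM principal
component covariates come from the full-sample GRM, matching the
motivating design), running the nested LRTs, converting binary-outcome
proportions to the liability scale per the prevalence map, pooling
per-cluster estimates, and recording one structured log line per fit
plus a manifest (seed, config hash, package version). Sex-stratified
runs drop sex from the covariate list. Failures in individual cells are
recorded and the grid continues. Everything is deterministic given the
configuration seed: per-stage seeds are derived from it by a string
hash, and two runs with the same seed produce byte-identical output
tables.

## Problem sizes used by the test suite

The statistical checks run at desk scale, chosen so Monte-Carlo error
sits well inside each tolerance on one core: model-4 recovery at
$n = 2000$, $m = 5000$ over 20 replicates (mean absolute deviation
tolerance 0.03); null calibration of the interaction LRT with 200 tests
(10 cohort designs × 20 phenotype redraws) at $n = 1000$; HE benchmarks
at $n = 2000$, $m = 5000$ over 10 replicates; the sex contrast at
$n = 1600$ over 20 replicates; and a five-cluster end-to-end determinism
check at $n = 750$. `scripts/acceptance.R` re-runs scaled versions of
the same computations from scratch and writes the headline quantities as
JSON.

## Known limitations

* SNPs are simulated unlinked; there is no LD, so MAF- or LD-dependent
  biases of GRM estimators cannot be studied with this generator.
* Binary traits use the observed-scale fit plus liability transformation
  rather than a probit mixed model; at extreme prevalences or very large
  components the linear approximation degrades.
* The ERM weights PCs equally; eigenvalue-weighted variants would change
  the kernel's effective rank.
* Per-cluster analyses assume clusters are exchangeable; the
  random-labels simulation cannot mimic genuine geographic
  stratification.
* Covariate-by-kernel interaction matrices are deliberately out of
  scope, as in the motivating design.
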