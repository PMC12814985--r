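---
title: "Kernel-weighted association testing of alternative polyadenylation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-weighted association testing of alternative polyadenylation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaptwas)
```

## The problem

Alternative polyadenylation (APA) lets a gene produce mRNA isoforms with
3'UTRs of different lengths, altering miRNA/RBP binding and hence mRNA
stability and translation without changing expression level. The per-gene,
per-sample **PDUI** (percentage of distal poly(A) site usage index)
quantifies this choice on a 0-1 scale. `kaptwas` tests, gene by gene,
whether the genetically regulated component of PDUI is associated with a
phenotype — a TWAS in which the molecular trait is 3'UTR usage rather than
expression, and in which the association stage is a kernel test able to
pick up non-additive SNP effects that a purely linear combination misses.

## The two-stage model

**Stage one — weights.** For each gene, cis SNPs within ±150 kb of the gene
start are regressed on PDUI,

$$\mathrm{PDUI} = \sum_{i=1}^{n} W_i\, G_i + \varepsilon,$$

with four estimators: ridge over all cis SNPs (the linear-kernel BLUP
equivalent, `blup`), elastic net with mixing 0.5 (`enet`), LASSO
(`lasso`), and the single best marginal SNP's OLS coefficient (`top1`).
Each is scored by five-fold cross-validation (squared Pearson correlation
between out-of-fold predictions and observed PDUI), and the best scorer is
kept. Ties are broken in the fixed order enet > lasso > blup > top1.

**Stage two — kernel test.** The selected coefficient vector forms a
diagonal weight matrix $W = \mathrm{diag}(W_1,\dots,W_n)$, used exactly as
estimated — signed, unstandardized, unrescaled. The weighted linear kernel

$$K_w = G W G^{\mathsf T}$$

defines the score statistic $Q = r^{\mathsf T} K_w r$, where $r = y - \hat\mu$
is the residual from an intercept-only null model (no covariates). Under
the null, $Q \sim \sum_i \lambda_i \chi^2_1$ with $\lambda_i$ the
eigenvalues of $V^{1/2} P_0 K_w P_0 V^{1/2}$; because the weights are
signed, $K_w$ may be indefinite and some $\lambda_i$ negative, which the
p-value machinery supports directly.

**Linear baseline.** The comparison method combines per-SNP GWAS z-scores
additively, $Z_{\mathrm{APA}} = w^{\mathsf T} z / \sqrt{w^{\mathsf T} R w}$ with $R$
an LD reference, two-sided normal p-value. The printed form of the
weighted z-score statistic has no variance normalization; without the
$1/\sqrt{w^{\mathsf T}Rw}$ factor it is not a z-score and admits no p-value, so
the standard TWAS normalization is applied.

## Numerical choices in the p-value

* The mixture tail $P(\sum_i \lambda_i \chi^2_1 > q)$ is computed by exact
  characteristic-function inversion (Imhof's integral), which handles
  signed eigenvalue sets. The spectrum is normalized to unit radius first
  — the tail is invariant under joint rescaling of $(q, \lambda)$, and
  without this the inversion integral can live at a numerically invisible
  scale when heavily shrunk weights make the spectrum tiny.
* The integral is evaluated adaptively on a truncated range (upper limit
  $2\times 10^4$ on the normalized scale, with a shorter fallback); the
  neglected oscillatory tail is far below the $10^{-9}$ accuracy target.
  If the quadrature fails, the Liu moment-matching approximation is used
  and tagged `liu` in the output.
* A single surviving eigenvalue short-circuits to the closed-form scaled
  chi-square tail (`exact_chisq`), which makes the single-SNP gene reduce
  exactly to the marginal score test.
* Eigenvalues below $10^{-10}$ of the spectral radius are dropped;
  p-values are floored at $10^{-12}$.
* For the weighted linear kernel the eigenvalues come from the
  $p \times p$ matrix $(P_0 G)^{\mathsf T}(P_0 G)\,\mathrm{diag}(w)$ rather than
  the $n \times n$ kernel (the nonzero spectra coincide), keeping per-gene
  cost at $O(np^2)$.

**Null variance treatment.** By default the variance scale is the plug-in
estimate ($\widehat{\sigma}^2$ for quantitative traits,
$\hat\mu(1-\hat\mu)$ for binary), the standard large-sample treatment.
`small_sample = TRUE` switches to an exact scale-free finite-sample null:
since $P(Q > q) = P\!\left(z^{\mathsf T} P_0 (K - cI) P_0 z > 0\right)$ with
$c = q / (r^{\mathsf T} r)$, the p-value is a mixture tail at zero over the
shifted spectrum. This removes the plug-in approximation and closely
tracks a phenotype-permutation null even at $n \approx 40$; it is the mode
to use when comparing against permutation references at small $n$. The two
modes agree to $O(1/n)$.

**Centering.** The score form is written without explicit covariates; an
uncentered $y$ breaks null calibration, so $Q$ uses the intercept-only
residual by default (`center = FALSE` exposes the raw form for
comparison).

## Binary traits

The intercept-only logistic null gives $\hat\mu$ = case fraction and
per-sample variance $\hat\mu(1-\hat\mu)$ in the eigenvalue weighting — the
standard kernel-test treatment for case-control data. Simulated binary
traits come from a liability-threshold rule: the continuous liability is
cut at its empirical $(1-\text{prevalence})$ quantile, so the realized
case count is exactly $\lfloor n \cdot \text{prevalence} \rfloor$.
Prevalence defaults to 0.5 (a balanced design maximizes case-control
information) and is configurable.

## What the simulator emulates

* **Genotypes** — two latent AR(1)-correlated standard-normal gametes per
  sample, thresholded at the MAF quantile and summed, give dosages in
  {0,1,2} with the requested marginal MAF (restricted to the post-QC
  regime [0.05, 0.5]) and a tunable LD decay `ld_rho`. This reproduces the
  two features that matter for the tests — allele frequency and local
  correlation — but not coalescent-grade haplotype structure, recombination
  hotspots or population stratification; conclusions about those features
  do not follow from these simulations.
* **Architectures** — additive with 2/5/10 causal SNPs (weights drawn
  N(0,1)), and four non-additive rules on carrier indicators
  (dosage ≥ 1): `single`, `epistatic` (both carriers required),
  `heterogeneous` (either carrier), `compensatory` (exactly one carrier;
  two variant alleles cancel). Carrier coding is used because the rules
  are statements about carrying a variant allele, not about dosage
  products; the rule magnitude is 1, since the heritability scaling
  absorbs any constant.
* **Heritability** — the empirical variance of the realized genetic value
  in each replicate is taken as $\sigma_g^2$ (not an analytic
  expectation), environmental noise is added with
  $\sigma_e^2 = \sigma_g^2 (1-h^2)/h^2$, so
  $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ holds per dataset.
* **Assumptions** — under *pleiotropy*, PDUI and phenotype are two
  independently noised copies of the same genetic value (heritabilities
  `h2_apa` and `h2_pheno`). Under *causality*, the phenotype is the noised
  PDUI: each stage of the genotype → PDUI → phenotype chain receives its
  own heritability, with the realized PDUI acting as the genetic value of
  the phenotype stage. We considered the alternative reading in which
  `h2_pheno` is the end-to-end genetic fraction of the phenotype, but it
  is infeasible whenever `h2_pheno > h2_apa` (a phenotype cannot be more
  heritable than the molecular trait that drives it), while the study
  grids cross both heritabilities over the same range; the stage-wise
  chain is the reading under which every grid cell is well defined.
* **Null design** — per-gene transcriptome surrogate and phenotype drawn
  iid N(0,1) with no genetic component at all; the full pipeline (weight
  training, model selection, both tests) runs on these to measure type-I
  error.
* **LD-aware causal selection** — `high_ld` draws a causal pair with
  empirical $r^2 > 0.8$, `low_ld` with $r^2 < 0.2$, computed on the
  simulated cohort itself.

All randomness derives from a single scenario seed through a fixed
linear-congruential stream-splitting rule, so any dataset, cell or
experiment is bit-reproducible from its configuration.

## Study grids and problem sizes

The shipped configurations mirror the study design: a pleiotropy grid of
7 architectures × 6 phenotype × 6 APA heritabilities
({0.01, 0.02, 0.04, 0.06, 0.08, 0.10}; 252 cells), a causality grid of
7 × 5 × 5 ({0.05, 0.10, 0.15, 0.20, 0.25}; 175 cells), and an extended
grid at {0.1, 0.2, 0.4, 0.6, 0.8}, each with 670 samples per dataset.
Power in a cell is the fraction of genes detected below the
Bonferroni-corrected threshold $\alpha/m$ with $m$ the number of genes in
the run (strict inequality); the empirical-cutoff alternative ranks null
p-values and takes the boundary of the most significant 5% (rank
$\lceil 0.05 N \rceil$).

The packaged checks run scaled-down versions of these designs chosen to
exercise every stage at meaningful precision: the null calibration uses
5,000 genes × 300 samples × 20 SNPs; the power-ordering comparison uses
the epistatic architecture under pleiotropy at matched low heritability
(`h2_pheno = h2_apa = 0.04` — the criterion pins the phenotype stage at
0.04 and the matched value is the least arbitrary choice for the APA
stage, placing the comparison in the noisy-weight regime where the two
methods genuinely differ) with 500 genes × 670 samples.

## Design decisions on open points

* **BLUP as CV-ridge.** The original BLUP weight trainer is invoked
  through external tooling without algorithmic detail; ridge regression
  over all cis SNPs with the penalty chosen by the same five-fold CV is
  the standard linear-kernel equivalent and keeps training
  self-contained. A REML variance-component BLUP would be the other
  defensible choice.
* **CV metric.** "Best prediction performance" is scored as out-of-fold
  squared correlation; for the penalized fitters one CV pass both selects
  the penalty and scores the model (the prevalidated predictions), the
  convention of the established TWAS weight trainers. A penalized fit
  whose selected coefficient vector is all-zero is scored 0 — its
  out-of-fold predictions are constants up to fold-intercept jitter, and
  letting that jitter win model selection would hand the association
  stage an empty weight vector.
* **MAF weighting.** The "diagonal weight matrix of minor allele
  frequencies" in the unweighted kernel variant has no stated functional
  form; the squared Beta(1, 25) density — the standard rare-variant
  up-weighting convention — is used.
* **Cis windows** are closed intervals anchored on the gene start
  (±150 kb, both ends inclusive), 1-based coordinates.
* **QC order** is SNP missingness (> 0.05 dropped), then sample
  missingness (> 0.05), then MAF (< 0.05 dropped, recomputed after sample
  drops); residual missing calls are mean-imputed, after which dosages
  are real-valued.
* **Degenerate genes.** A constant PDUI trains to all-zero weights with a
  warning; an all-zero weight vector makes the kernel test return p = 1
  (flagged `degenerate`) and the linear statistic undefined (`NA` in the
  pipeline, counted as a non-detection).

## Known limitations

* Covariate adjustment is deliberately absent (intercept-only null);
  stratified cohorts need external residualization first.
* Rare variants are out of scope: QC removes MAF < 0.05 and the generator
  works in the post-QC regime.
* The weighted linear kernel with signed weights is indefinite in
  general; only symmetry is guaranteed. A spectrum that is wholly
  non-positive cannot be inflated by any association, so the statistic is
  negated in that case (its rejection tail is always the tail signal
  pushes toward); for genes whose evidence concentrates in one tagged SNP
  the kernel test and the linear baseline reduce to the same marginal
  evidence.
* p-values below ~1e-8 from the inversion inherit the quadrature's
  absolute error; they are floored at 1e-12 rather than reported to
  higher precision.
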