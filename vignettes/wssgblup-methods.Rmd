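---
title: "Weighted single-step GBLUP and window-based association mapping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GBLUP methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Breed societies score visible defects — here, progressive vitiligo-like
depigmentation around the eyes, mouth and nostrils of horses — on a 1–9
linear scale during a once-in-a-lifetime registration assessment. Most
animals are unaffected, so the scores are heavily zero-inflated ordinal
data. Only a subset of the pedigree is genotyped, on two different SNP
arrays. The analysis task is to estimate variance components and breeding
values for these traits jointly, convert the genomic breeding values into
per-SNP effects, and scan the genome in 1-Mb windows for regions explaining
an outsized share of the additive genetic variance.

`wssgblup` implements that chain — weighted single-step GBLUP (wssGBLUP)
with a window-based association scan — as reusable, tested components, plus
a synthetic-data generator with the same statistical structure so the whole
pipeline can be exercised without access to any proprietary studbook data.

## The model

The phenotypes follow a multivariate repeatability animal model

$$y = Xb + Za + Wp + e$$

with fixed effects $b$ (sex, age class, coat colour, geographic area, and
inbreeding $F$ as a linear covariate), additive genetic effects
$a \sim N(0,\, G_0 \otimes H)$, permanent-environment effects
$p \sim N(0,\, I\sigma^2_p)$ and residuals $e \sim N(0,\, R_0 \otimes I)$.
The 1–9 scores are analyzed as linear observations; no threshold link is
used in fitting, mirroring standard practice for these routine evaluations.

$H$ combines pedigree and genomic information. Its inverse is sparse:

$$H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{pmatrix}$$

where $A$ is the numerator relationship matrix, $A_{22}$ its genotyped
block, and $G = Z D Z' / \sum_j 2 p_j (1-p_j)$ the (weighted) genomic
relationship matrix from centred gene content, with $D$ a diagonal matrix of
per-SNP weights, initially $I$.

SNP effects are obtained from the GEBVs of the genotyped animals by
back-solving, and weights are updated from the solutions:

$$\hat g = D Z' G^{-1} \hat u \big/ \textstyle\sum_j 2p_j(1-p_j), \qquad
  w_j = \hat g_j^2 \, 2 p_j (1 - p_j),$$

after which $G$, the model solutions, and $\hat g$ are recomputed (two
rounds by default). The percentage of additive variance attributed to a
1-Mb window anchored at each SNP is

$$\mathrm{Var}\!\left(\sum_{j \in \text{window}} Z_j \hat g_j\right) \Big/
  \sigma^2_a \times 100\%$$

computed over genotyped animals with the $n-1$ sample variance. Windows
explaining strictly more than 1% are flagged, and overlapping flagged
windows merge into reported regions.

### Back-solving: the printed formula vs the implemented one

The source formula for SNP effects is sometimes printed as
$\hat g = Z'(Z'Z)^{-1}\hat u$, which is dimensionally inconsistent when the
SNP count exceeds the animal count. The package implements the standard
back-solving form $\hat g = D Z' G^{-1}\hat u / \sum 2p(1-p)$ (the two
coincide on a single-SNP toy case, which the tests verify). When $G$ is
singular — fewer informative SNPs than animals, or an unblended toy matrix —
a Moore–Penrose pseudo-inverse is used.

## Estimation

Variance components are estimated by REML. Two algorithms share one
likelihood implementation built on Henderson's mixed-model equations:

* **EM** (default): the classical expectation–maximization updates. The
  restricted log-likelihood is non-decreasing across iterations; this is a
  tested invariant. EM is robust but approaches boundaries slowly.
* **AI**: average-information updates with scores computed from the same
  MME quantities, verified against EM at interior optima. Steps proposing a
  non-positive-definite covariance are projected onto the parameter space
  (eigenvalue floor $10^{-8}$), so null components pin at the boundary
  quickly; if no damped step is admissible the iteration falls back to EM.

Up to three traits are supported with a shared fixed-effect design.
Trait-wise missing records are handled by per-pattern residual blocks in
the MME and the likelihood; the exact EM residual update applies to
complete records, and for incomplete records the observed-pair
approximation is used (monotonicity is then not guaranteed, and AI falls
back to EM). With single records per animal the permanent-environment
variance is confounded with the residual; the default (`pe = "auto"`) drops
the PE term in that case.

Convergence is declared when the maximum relative parameter change falls
below `tol` (default 1e-6, `max_iter` 500). Variances are floored at 1e-8.
Standard errors of $h^2$ and $r_g$ are reported as not available rather
than approximated.

### Numerical choices

* Fixed factors are dummy-coded with the **last level as reference**;
  covariates are centred. A rank-deficient fixed block is an error naming
  the confounded columns.
* $G$ is tuned to $A_{22}$ by two-coefficient moment matching (mean
  diagonal and mean off-diagonal) and blended as
  $\alpha G + (1-\alpha)A_{22}$, $\alpha = 0.95$ by default, which
  guarantees invertibility. No $\tau/\omega$ scaling of the genomic block
  is applied (hooks default to 1).
* $A^{-1}$ is assembled sparsely by Henderson's rules with inbreeding
  ($d_i = 1 - \tfrac14(1+F_s) - \tfrac14(1+F_d)$, unknown-parent terms
  dropped); inbreeding itself comes from the tabular relationship
  recursion, an $O(n^2)$ method accepted at desk scale (capped at 5000
  animals). Unknown parents contribute relationship 0; there are no
  unknown-parent groups.
* Missing genotypes are mean-imputed (0 after centring); the counted-allele
  frequency is used in $2p(1-p)$, equivalent to the minor-allele form.
* Call-rate QC keeps a SNP at exactly the threshold ("below 95%" is
  strict), and region selection requires strictly more than the 1%
  threshold.

## The synthetic-data generator

The generator emulates the study design: a discrete-generation pedigree
(default 5 generations — the source population averages 5.7 complete
generations), gene-dropped biallelic SNPs, and one to three traits with
target heritabilities (defaults 0.17/0.13/0.28), genetic correlations
(defaults 0.55/0.52/0.79) and zero-inflated 1–9 scores with stated
absent/slight/severe prevalences. Marker density defaults to ~27 SNPs/Mb,
matching a ~60K equine panel over ~2.4 Gb; this matters because 1-Mb
windows must hold realistic SNP counts.

Design choices a reader should know:

* **No linkage disequilibrium.** SNPs segregate independently given the
  pedigree. Consequently a causal variant cannot be tagged by neighbours,
  so each configured QTL is realized as a **cluster of 5 causal SNPs
  inside its 1-Mb window**, standing in for the LD block a real variant
  would tag. With a single causal SNP and no LD, back-solving provably
  spreads the signal across the whole panel and the window scan cannot see
  it even with perfect breeding values.
* **The polygenic remainder lives on the markers** by default
  (`polygenic_mode = "markers"`): small correlated effects at every
  non-QTL SNP. This matches the single-step model's premise that a dense
  panel carries the additive variance. The alternative
  (`"pedigree"`) transmits a marker-independent polygene with Mendelian
  sampling; a genomic relationship matrix cannot tag such variance, and
  fully-genotyped analyses of that world are biased downward in $h^2$ —
  a useful mis-specification scenario, but not a recovery benchmark.
* **The generator states its world exactly.** Realized component variances
  are rescaled to their targets, the polygene is whiten–recoloured to the
  exact target correlation matrix, and residuals are orthogonalized
  against the genetic values, so realized $h^2$ and $r_g$ equal the
  configured truth. Estimation noise is left entirely to the estimator.
* **Ordinal scores come from a liability-threshold construction** even
  though the fitter is linear — the same mismatch the real analysis
  embodies. Thresholds are placed from the liability's model variance to
  hit the target prevalences, with the slight (2–5) and severe (6–9) mass
  split geometrically across sub-scores. A green recovery test on the
  liability scale therefore does not establish unbiasedness on the
  observed ordinal scale.

What a green test establishes: the estimation and scanning machinery
recovers the parameters of data generated under its own assumptions
(plus the stated threshold mismatch). What it does not establish:
performance under real LD, selection, assortative mating, genotyping
error, or the real study's scale.

## Known limitations

* Dense $G$, $A$ and MME solvers cap practical size at a few thousand
  animals (configurable caps); there is no APY-style approximation.
* REML recovery of a weakly identified component is honest but noisy: with
  an $h^2 = 0.13$ trait at $n = 1000$, the additive covariance likelihood
  can peak on the $r_g = 1$ boundary. The genetic-correlation recovery
  benchmark therefore uses two $h^2 = 0.28$ traits.
* The null hypothesis "additive variance is zero with $H = I$" is only
  testable with repeated records (with single records $\sigma^2_a$ and
  $\sigma^2_e$ are confounded and EM stalls at its starting ratio); the
  acceptance test implements the identifiable repeated-records version.
* Pedigree pruning is not implemented (runs use the full pedigree).
* Window spans are anchored at each SNP and extend forward
  `window_bp - 1` bp, never crossing chromosomes; variance contributions
  of overlapping windows are not additive (LD covariance), and only
  non-negativity is asserted.
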