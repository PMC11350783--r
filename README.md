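# wssgblup

Weighted single-step GBLUP (wssGBLUP) and SNP-window association analysis
for pedigreed populations with partial genotyping, in R.

The package was built around a concrete use case: mapping the genetic basis
of vitiligo-like depigmentation in a horse breed whose studbook scores the
defect 1–9 (heavily zero-inflated: >79% of animals score 1) around the
eyes, mouth and nostrils, with a deep pedigree and a few thousand animals
genotyped on two merged SNP arrays. Everything is reusable for any
quantitative or ordinal-scored trait with the same data shape.

## What it computes

For traits following the multivariate animal model
*y = Xb + Za + Wp + e*, with *a ~ N(0, G₀ ⊗ H)*:

* **Pedigree machinery** — validated/topologically sorted pedigrees,
  inbreeding F, the numerator relationship matrix A (diag = 1 + F), its
  sparse inverse by Henderson's rules, and the genotyped block A₂₂.
* **Genomic machinery** — PLINK text/binary I/O, panel merging on common
  markers with allele flipping, strict call-rate QC (< 95% discarded),
  centred gene content Z, and the weighted genomic relationship matrix
  G = ZDZ′ / Σ 2pⱼ(1−pⱼ), tuned/blended with A₂₂ for invertibility.
* **Single-step H⁻¹** — A⁻¹ plus the genotyped-block correction
  G⁻¹ − A₂₂⁻¹.
* **REML** — multivariate (≤3 traits) variance components by EM (monotone)
  or average-information updates; heritabilities
  h² = σ²ₐ/(σ²ₐ+σ²ₚ+σ²ₑ) and genetic correlations r_g.
* **wssGWAS** — back-solving GEBVs to SNP effects
  ĝ = DZ′G⁻¹û / Σ2p(1−p), quadratic re-weighting wⱼ = ĝⱼ²2pⱼ(1−pⱼ)
  (two rounds by default), sliding 1-Mb window percentages of additive
  variance, strict >1% significance, region merging, Manhattan export.
* **Synthetic data** — gene-dropping simulator of pedigrees, genotypes and
  correlated zero-inflated ordinal phenotypes with stated heritabilities,
  genetic correlations and prevalences, so the full chain runs with no
  external data.

## Worked example

Simulate a nostril-like trait (h² = 0.28, one QTL explaining 40% of the
additive variance in the 1-Mb window centred at 4 Mb on chromosome 2) and
run the full weighted single-step chain:

```r
library(wssgblup)

cfg <- sim_config(n_founders = 100, n_generations = 4, n_snps = 1000,
                  n_chromosomes = 5, chrom_length_bp = 8e6,
                  traits = "VN", h2_targets = 0.28,
                  rg_matrix = matrix(1, 1, 1),
                  prevalence = list(c(0.82, 0.14, 0.04)),
                  pe_variance = 0, observed = "liability",
                  qtl_spec = data.frame(chrom = 2, center_bp = 4e6,
                                        frac = 0.4),
                  genotyped_fraction = 0.8, seed = 7001)
dat  <- simulate_dataset(cfg)
spec <- model_spec("VN", factors = c("sex", "age", "coat", "area"),
                   covariates = "F")
res  <- run_wssgblup(dat$ped, dat$geno, dat$pheno, spec,
                     n_iter = 2, reml_method = "ai")

cat("sigma2_a =", round(res$vc$G0[1,1], 3),
    " sigma2_e =", round(res$vc$R0[1,1], 3),
    " h2 =", round(heritability(res$vc), 3), "\n")
res$regions[order(-res$regions$max_pct), ][1:3, ]
```

Output (as printed by the code above):

```
sigma2_a = 0.355  sigma2_e = 0.653  h2 = 0.352
 chrom start_bp  end_bp max_pct n_windows
     2  2800982 7371258  11.354        91
     1    20293 7989453   8.570       145
     2   101612 2198138   4.289        27
```

The REML heritability estimate (0.35) sits near the simulated truth (0.28;
single-seed sampling noise at n = 500), and the top-ranked region — 11.4%
of additive variance after the second weighting round — contains the true
QTL window (chromosome 2, 3.5–4.5 Mb). Region spans are merged runs of
overlapping significant 1-Mb windows, so they are wider than a single
window.

A command-line front-end covering simulate / qc / relmat / run / report is
in `inst/cli/wssgblup.R`, configured by YAML (call-rate threshold 0.95,
1-Mb windows, 1% threshold and two weighting rounds are the defaults).

## Documentation

The methods vignette (`vignettes/wssgblup-methods.Rmd`) explains the model,
the estimation algorithms, every numerical default, what the synthetic
generator does and does not emulate, and the package's known limitations.
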