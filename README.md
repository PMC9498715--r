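# holopred

Holo-omic prediction of complex traits: joint modelling of a host's SNP
genotypes and its microbiome composition to predict phenotypes such as
milk yield, methane emission or feed conversion, and to ask the question
that motivates the field — *does modelling a genome-by-microbiome
interaction buy prediction accuracy over additive models?*

The package is aimed at quantitative geneticists and microbiome
researchers who work with livestock-style cohorts (a few hundred animals,
dense biallelic SNP arrays, 16S OTU tables) and want the five standard
model families fitted, cross-validated and compared with one consistent,
fully reproducible toolchain.

## The models

All five are Bayesian linear mixed models differing only in their random
terms:

| label | model | random terms |
|---|---|---|
| `genomic`   | y = Xβ + Zγ + g + e             | g ~ N(0, G σ²g) |
| `microbial` | y = Xβ + Zγ + m + e             | m ~ N(0, M σ²m) |
| `direct`    | y = Xβ + Zγ + g + m + e         | both |
| `core`      | y = Xβ + Zγ + g + m + gcmc + e  | + N(0, Kc σ²gm) |
| `hadamard`  | y = Xβ + Zγ + g + m + ghmh + e  | + N(0, (G∘M) σ²gm) |

* **G** is the VanRaden genomic relationship matrix
  `G = (Z − 2Q)(Z − 2Q)ᵀ / Σ 2pₘ(1 − pₘ)` from MAF-filtered dosages;
* **M** is the microbial relationship matrix `M = RRᵀ/q` from
  log-transformed, per-OTU standardised relative abundances of
  prevalence-filtered OTUs;
* **G∘M** is the entry-wise (Hadamard) product — a PSD interaction kernel
  by the Schur product theorem;
* **Kc = ½(L_G L_Mᵀ + L_M L_Gᵀ)** is the symmetrised Cholesky
  cross-product (the CORE-GREML-style covariance between the two random
  effects), which satisfies Kc = G when M = G.

Fixed covariates (farm, age, weight) get flat priors; class effects
(diet, pen, slaughter day) are dummy-coded and fitted under a BayesB
mixture prior; kernel effects are RKHS terms sampled in the kernel
eigenbasis. Models are scored by 10-fold cross-validation repeated ten
times, accuracy being the squared Pearson correlation r² between
predicted and observed phenotypes of the validation folds, and compared
by one-way ANOVA with Tukey HSD at α = 0.05. A synthetic holo-omic
generator with exactly this variance structure makes every stage testable
without animal data. See `vignette("holo-omics-prediction")` for the
methods and every numerical design choice.

## Worked example

```r
library(holopred)

params <- sim_params(n_samples = 250, n_snps = 600, n_otus = 150,
                     var_g = 0.25, var_m = 0.30, var_gm = 0.15, var_e = 0.30,
                     seed = 2024)
sim <- simulate_holoomics(params)
#> <holo_sim> 250 samples, 600 SNPs, 150 OTUs; fractions g/m/gm/e = 0.25/0.3/0.15/0.3 (seed 2024)

kernels <- build_kernel_set(sim$genotypes, sim$otus,
                            models = c("genomic", "hadamard"))
kernels$G
#> <holo_kernel GRM> 250 x 250, mean diagonal 1.0000

fit <- holo_fit(build_model(sim$phenotypes, "hadamard", kernels),
                sim$phenotypes,
                mcmc_settings(n_iter = 3000, burn_in = 1000, seed = 1))
fit
#> <holo_fit 'hadamard'> trait 'y', 250 samples (0 predicted), 400 kept draws
#>       term post_mean    post_sd
#>   sigma2_g 0.2431740 0.07833363
#>   sigma2_m 0.3102366 0.09066905
#>  sigma2_gm 0.1482571 0.05938720
#>   sigma2_e 0.3918795 0.08222802
```

The posterior variance components sit near the simulated fractions
(0.25/0.30/0.15/0.30): the genomic share is the heritability analogue,
the microbial share the microbiability, and `sigma2_gm` the
interaction-kernel share. Cross-validated accuracy then quantifies what
the interaction buys in prediction:

```r
folds <- make_folds(250, k = 10, repeats = 2, seed = 11)
st <- mcmc_settings(n_iter = 600, burn_in = 200, thin = 2, seed = 12)
cv_g <- cross_validate(sim$phenotypes, "genomic", kernels, folds, st)
cv_h <- cross_validate(sim$phenotypes, "hadamard", kernels, folds, st)
cv_g
#> <holo_cv 'genomic'> mean r2 = 0.212 +/- 0.027 over 2 repeats x 10 folds
cv_h
#> <holo_cv 'hadamard'> mean r2 = 0.342 +/- 0.004 over 2 repeats x 10 folds

compare_models(list(cv_g, cv_h))
#> <holo_comparison> one-way ANOVA F = 44.969, p = 0.0215 (alpha = 0.05)
#>              pair      diff        lwr      upr      p_adj significant
#>  hadamard-genomic 0.1301872 0.04672836 0.213646 0.02139592        TRUE
```

On data simulated with a genome-by-microbiome interaction the
interaction-aware model out-predicts genomic-only prediction by ~0.13 r²
here, and the ANOVA flags the difference at α = 0.05.
`plot_model_comparison()` draws the grouped accuracy bar chart;
`run_pipeline(run_config(...))` chains filtering, kernel construction, CV
and comparison end to end and writes every artifact (kernels, CV tables,
comparison, run metadata) deterministically from three named seeds.

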