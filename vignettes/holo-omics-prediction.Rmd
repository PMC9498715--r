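---
title: "Holo-omic prediction models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holo-omic prediction models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A growing body of livestock work predicts complex traits — milk yield,
methane emission, feed conversion — not from the host genome alone but from
the *hologenome*: the host's SNP genotypes together with the composition of
its gut or rumen microbiome. holopred implements the five standard model
families for this setting and the machinery to compare them honestly:

| label | linear predictor | interaction kernel |
|---|---|---|
| `genomic`   | $y = X\beta + Z\gamma + g + e$ | — |
| `microbial` | $y = X\beta + Z\gamma + m + e$ | — |
| `direct`    | $y = X\beta + Z\gamma + g + m + e$ | — |
| `core`      | $y = X\beta + Z\gamma + g + m + g_c m_c + e$ | Cholesky cross-product |
| `hadamard`  | $y = X\beta + Z\gamma + g + m + g_h m_h + e$ | $G \circ M$ |

with $g \sim N(0, G\sigma^2_g)$, $m \sim N(0, M\sigma^2_m)$, the interaction
term $\sim N(0, K\sigma^2_{gm})$ for its kernel $K$, and
$e \sim N(0, I\sigma^2_e)$. $X\beta$ holds fixed covariates (farm, age,
weight); $Z\gamma$ holds class effects (diet, pen, slaughter day) fitted
under a BayesB mixture prior.

# Kernels

**GRM.** The VanRaden genomic relationship matrix
$$G = \frac{(Z - 2Q)(Z - 2Q)^\top}{\sum_m 2 p_m (1 - p_m)},$$
with $Z$ the $n \times p$ dosage matrix and $p_m$ the ALT-allele frequency
of SNP $m$. Frequencies are computed from the sample; missing calls are
mean-imputed to $2p_m$ (the imputation consistent with this centring).
SNPs are pre-filtered at MAF $\ge$ 0.01, the usual array QC floor.

**MRM.** OTU counts become per-sample relative abundances; exact zeros are
replaced by half the smallest nonzero relative abundance of the whole table
(a log transform needs a pseudocount, and this choice adapts to the table's
depth); abundances are log-transformed and each OTU column is centred and
scaled to unit variance; then $M = RR^\top / q$ over the $q$ retained OTUs.
Standardisation is per OTU, not per sample: it matches common
microbial-relationship-matrix practice and makes the mean diagonal of $M$
close to one. OTUs are pre-filtered at 20% prevalence, and zero-variance
log-abundance columns are dropped with a warning (they carry no contrast).

**Hadamard interaction.** $K_h[i,j] = G[i,j]\,M[i,j]$. By the Schur
product theorem $K_h$ is positive semidefinite whenever $G$ and $M$ are,
so it is a valid covariance for a genome-by-microbiome interaction effect.

**Cholesky cross-product (CORE).** To model *covariance between* the
genomic and microbial random effects, following the CORE-GREML idea of
fitting Cholesky factors of the two covariance matrices, we define
$$K_c = \tfrac12\,(L_G L_M^\top + L_M L_G^\top), \qquad
G = L_G L_G^\top,\; M = L_M L_M^\top.$$
The symmetrisation makes $K_c$ usable as a kernel and the factor
$\tfrac12$ gives the self-consistency identity
`core_greml_kernel(G, G) = G`, which the test suite enforces to 1e-8.
Unlike the other kernels $K_c$ may be indefinite; its smallest eigenvalue
is recorded on the object, and the sampler truncates negative eigenvalues
to zero with a message. If a factorisation fails numerically, a ridge
$\varepsilon I$ is escalated deterministically from 1e-10 by tens up to
1e-6 before giving up.

**Normalisation.** All kernels are divided by their mean diagonal before
fitting (`normalise_kernel()`). Variance components attached to kernels on
different scales are not comparable — a raw Hadamard kernel in an
unstructured population has a shrunken diagonal — and the unit-diagonal
convention makes $\sigma^2$ estimates read as shares of phenotypic
variance. Reported interaction components are variances attached to the
interaction kernel, not signed covariances; a Gibbs variance draw cannot be
negative, so a genuinely negative genome–microbiome covariance is outside
this parameterisation (a known limitation of the whole model family).

# The Gibbs sampler

`holo_fit()` samples the joint posterior with scalar/block conjugate
updates:

* **Fixed effects** get a flat prior and a joint multivariate-normal
  update from the precomputed Cholesky factor of $X^\top X$ (aliased
  columns are dropped by QR).
* **Class effects** are dummy-coded indicator columns under the BayesB
  mixture: zero with probability $\pi$, otherwise normal with a per-column
  variance following a scaled-inverse-$\chi^2(\nu_b, S_b)$ prior. Fitting
  categorical terms with a marker-selection prior is unusual but is the
  convention of this model family; `class_effects = "gaussian"` is the
  escape hatch that fits one common variance per term instead.
* **Kernel (RKHS) effects** are sampled in the eigenbasis of their kernel:
  with $K = UDU^\top$ (eigenvalues below $10^{-8}\times$ the largest
  truncated), $u = U\alpha$ and the whole $\alpha$ vector has a diagonal
  conditional covariance, so the update is one joint vectorised draw. Each
  sweep costs two $n\times q$ matrix–vector products per kernel.
* **Variance components** and the residual variance follow
  scaled-inverse-$\chi^2$ updates. Any component can be pinned with
  `fix_variances`, which is how the closed-form BLUP equivalence check is
  run.
* **Masked phenotypes** (`NA`) are handled by data augmentation: each
  sweep redraws them from $N(\text{lp}, \sigma^2_e)$. This is exact Gibbs
  for the posterior given the observed entries only, keeps validation
  animals inside the kernels (which is what makes whole-kernel
  cross-validation prediction work), and preserves the orthonormality that
  makes the eigenbasis update a single vectorised draw. A consequence the
  tests exploit: at every sweep the fitted components and residuals
  reconstruct the (augmented) phenotype exactly.

**Priors and defaults.** Chain defaults are BGLR-like: 12,000 sweeps,
2,000 burn-in, thinning 5; $\pi = 0.5$; all variance-prior df 5. Prior
scales follow an expected-proportion-of-variance rule: the prior mode of
each random term's variance is set to `r2_prior` (default 0.5) times the
phenotypic variance split evenly over the random terms, and the residual
prior mode to the remainder. These are weakly informative at study-scale
$n$; the shrinkage test in the suite runs at $n = 400$ precisely so the
likelihood, not the prior, decides.

# Cross-validation and model comparison

`make_folds()` builds balanced random partitions (fold sizes differ by at
most one); 10 folds repeated 10 times is the convention implemented, read
as ten *independent* repeats of a full 10-fold split — that is what gives
the ten repeat-level accuracies the ANOVA consumes. Folds are not
stratified by farm or pen (the plain reading of a random foldid vector).
Accuracy is the squared Pearson correlation $r^2$ between predictions and
the raw observed phenotypes of the validation fold, not pre-adjusted
residuals. `compare_models()` runs a one-way ANOVA on the per-repeat
$r^2$ values followed by Tukey HSD (the default companion of a one-way
ANOVA when only "multiple comparisons" is specified) at $\alpha = 0.05$.
Reported spread is the SD of per-repeat values; the standard error is
available via `glance()`.

A statistical caveat the suite accounts for: under a pure-noise null,
$E[r^2] \approx 1/(n_{val} - 1)$. With 10 folds, a mean null $r^2$ below
0.05 therefore needs validation folds of 40+ samples, i.e. $n \ge 400$ —
the scale at which the null-calibration check runs.

# The synthetic generator

`simulate_holoomics()` emulates the structure of the two livestock data
styles this model family is applied to (cattle-style: farm + diet; n in
the low hundreds; dense biallelic SNPs; 16S OTU tables):

* genotypes are per-SNP Binomial(2, $p_m$) with $p_m$ uniform on
  `maf_range` (default 0.05–0.5); SNPs whose realised MAF falls below the
  0.01 QC floor are redrawn;
* OTU counts are Dirichlet-multinomial around a heterogeneous base
  composition (base proportions from a sparse Gamma draw), so compositions
  are overdispersed and the default concentration of 0.1 per OTU leaves
  the 20% prevalence filter with real work;
* the genomic, microbial and interaction components are drawn with exact
  covariances $\sigma^2_g G$, $\sigma^2_m M$, $\sigma^2_{gm} (G \circ M)$,
  where the kernels are computed *from the simulated data themselves* and
  normalised to unit mean diagonal. The microbial kernel used for
  generation is built on the prevalence-filtered community — the
  component is defined on the measured microbiome, the same object the
  analysis pipeline fits — otherwise filtering would attenuate every
  recovery check for reasons that have nothing to do with the sampler.
* the interaction is generated under the Hadamard kernel. No generative
  mechanism for a genome-microbiome interaction is settled biology; the
  Hadamard choice makes "interaction-aware models out-predict additive
  ones" a property that can be switched on (`var_gm > 0`) and off, which
  is exactly what the ranking tests need. By default $g$ and $m$ are
  independent; `gm_correlation` mixes a shared latent draw into $m$ to
  exercise the covariance (CORE) term, and `missing_rate` punches random
  holes in the genotypes to exercise imputation.

Variance fractions must sum to one, so simulated phenotypes have unit
total random variance; fixed farm effects (evenly spaced over ±0.5) and
diet effects (±0.3) sit on top.

What the generator does **not** emulate: linkage disequilibrium and
pedigree structure (SNPs are independent, individuals unrelated),
read-level 16S error, and real compositional covariance networks. Two
consequences matter for interpreting green tests. First, with unrelated
individuals the off-diagonals of $G$ are $O(1/\sqrt{p})$, so the Hadamard
kernel is close to the identity and the simulated interaction component is
nearly unpredictable — interaction models win on interaction data mainly
through better variance partitioning, not through predicting the
interaction itself; in real cattle data with related animals the
interaction kernel carries more off-diagonal structure. Second, passing
recovery tests show the *sampler* is correct under its own model, not that
the model describes any particular real population.

# Problem sizes and runtimes

The test suite and the acceptance script size their simulations as a
deliberate compromise: oracle checks run on matrices up to 8×8 (where
naive double-loop arithmetic is exact and instant); sampler equivalence
checks at $n = 100$; variance-recovery and null-calibration checks at
$n = 400$ with 1,000 SNPs / 200 OTUs (recovery) — the smallest scale at
which the likelihood dominates the priors and null $r^2$ sits clearly
below 0.05; ranking checks at $n = 250$ with reduced chains (500–600
sweeps), which repeated trials show is enough for the ranking properties
to be stable across seeds.

# Known limitations

* Variance components for interaction kernels are reported as variances,
  never signed covariances (see above).
* REML/frequentist fits, multi-trait models, Kronecker-product kernels and
  phylogeny-aware microbial kernels (UniFrac) are out of scope.
* BayesB hyperparameters ($\pi$, df, scale) are fixed, not estimated;
  they are settings, and the ridge-limit test pins their semantics.
* The package's interface is R functions plus `run_pipeline()` — the unit
  a practitioner scripts against; there is deliberately no shell
  executable.
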