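# gxeherit

Randomized Haseman–Elston estimation of gene–environment (GxE) interaction
heritability from genome-wide SNP data and multiple measured environmental
variables.

## What it does

When many environmental variables are measured per individual, the
interesting quantity is often not the interaction of the genome with any
single one of them, but the share of phenotypic variance explained by
genome-wide SNP-by-environment interactions overall — and, if interactions
act through a combination of environments, which combination.  `gxeherit`
provides two method-of-moments estimators built on Hutchinson stochastic
trace estimation, so the N×N kernel matrices are never formed and genotypes
are streamed from PLINK BED files in standardized blocks:

- **`memma()`** fits the per-environment model
  `y ~ N(Cα, σ_β² K + Σ_l σ_wl² (F_l F_lᵀ/M) + σ_e² I)`
  with `K = XXᵀ/M` and `F_l = diag(E_l) X`, solving the randomized
  Haseman–Elston normal equations `Tθ = c` analytically
  (`T_kl = tr(WK_kWK_lW)`, `c_k = yᵀWK_kWy`, with covariate projection
  `W = I − C(CᵀC)⁻¹Cᵀ`).

- **`gplemma()`** fits the constrained single-score model
  `y ~ N(Cα, σ_β² K + K₂(w̃) + σ_e² I)` with
  `K₂(w̃) = diag(Ew̃) K diag(Ew̃)`, jointly estimating the linear
  environmental score `η = Ew` and its GxE heritability by minimizing
  `S(θ) = ‖Wyyᵀ W − Cov(y)‖_F²` with a multistart Levenberg–Marquardt
  algorithm.  Per-component heritability is reported as
  `ĥ²_k = θ̂_k tr(WK_kW) / Σ_j θ̂_j tr(WK_jW)`.

A full simulation framework (`simulate_dataset()` and friends) generates
genotypes, Gaussian or ordinal environments, and three phenotype classes
(baseline single score, three orthogonal scores, and a misspecified
phenotype with a squared heritable environment) with exact, recorded
variance decompositions, plus a pre-screen for squared environmental
effects (`squared_effect_screen()`).

## Worked example

```r
library(gxeherit)

cfg <- sim_config(N = 2000, M = 4000, L = 8, L_active = 4, M_G = 100,
                  M_GxE = 50, h2_g = 0.20, h2_gxe = 0.05, covar_frac = 0.01,
                  seed = 1)
sim <- simulate_dataset(cfg)      # genotypes, environments, PC1, phenotype
fit <- gplemma(sim$y, sim$geno, sim$E, sim$C, probes = 50, restarts = 10,
               seed = 2)
fit
#> GPLEMMA non-linear randomized Haseman-Elston fit
#>   N = 2000  M = 4000  L = 8  D = 10  B = 50
#>   h2 (main): 0.1784   h2 (GxE): 0.09171   residual: 0.7298
#>   squared error S = 3877401  (best of 10 restarts, tolerance )

round(fit$es_weights, 3)
#>   env1   env2   env3   env4   env5   env6   env7   env8
#>  0.762 -0.198  0.291 -0.443 -0.067 -0.119  0.093 -0.270
abs(cor(fit$eta_hat, sim$truth$eta_true))
#> [1] 0.872
```

The simulated trait has main-effect heritability 20%, GxE heritability 5%
through a score over environments 1–4, and a covariate explaining 1% of
variance.  At this deliberately small size the fit recovers the main
component (17.8% vs 20%) and the score direction (|correlation| 0.87 with
the true η), while the GxE share (9.2% vs 5%) shows the upward
finite-sample bias of a non-negative, weight-adaptive variance estimate —
it tightens as N grows relative to L.  The per-environment decomposition
from the same data:

```r
memma(sim$y, sim$geno, sim$E, sim$C, probes = 50, seed = 2)
#> MEMMA randomized Haseman-Elston fit
#>   N = 2000  M = 4000  L = 8  D = 10  B = 50
#>   h2 (main)      : 0.1744
#>   h2 (GxE total) : 0.1419
#>   residual       : 0.6837
```

MEMMA's unconstrained per-environment components have larger spread than
GPLEMMA's constrained fit (its *raw*, signed solution in `$pve_raw` is the
unbiased object suitable for averaging across replicates); it cannot
recover score weights or their signs.

A command-line front end with `simulate`, `memma` and `gplemma`
subcommands is installed at `inst/scripts/gxeherit`.

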