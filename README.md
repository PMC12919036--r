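# mvharmonize

Multivariate batch-effect harmonization for multi-metric panel data.

Multi-site studies pool measurements in which each *feature* (e.g. a
cortical region of interest) carries several biologically coupled *metrics*
(e.g. thickness, surface area, curvature). Site/scanner batch effects then
live not only in the mean and variance of each measurement but also in the
covariance between metrics — and per-feature harmonizers such as classical
ComBat leave those covariance effects behind.

`mvharmonize` models the cross-metric residual vector of every feature
jointly. With Y_ijvm = α_vm + X_ij'β_vm + Z_ijvm and the stacked residual
Z_ijv ∈ R^M per feature,

    Z_ijv ~ N(γ_iv, Σ_iv)          per batch i,

**MV-ComBat** places conjugate priors γ_iv ~ N(γ̄_i, T_i),
Σ_iv ~ IW(Ψ_i, ν_i) with method-of-moments hyperparameters, computes the
posterior means (γ*_iv, Σ*_iv) by a joint fixed-point iteration, and
whitens each residual with the symmetric inverse square root,
Z*_ijv = Σ*_iv^{-1/2}(Z_ijv − γ*_iv), before restoring scale and fixed
effects. An MCMC estimator (LKJ correlation prior, half-t scales, partial
pooling of γ across features) replaces the plug-in EB when decoupled
shrinkage of scales and correlations is wanted. **MV-CovBat** adds a
second-stage harmonization of a shared orthonormal latent subspace G
(top eigenvectors of S = Σ_m F^(m)F^(m)', the Rayleigh–Ritz solution of
min Σ_m ‖F^(m) − G A^(m)‖²_F) estimated across metric-wise PCA scores, to
remove covariance batch effects across features and metrics. Univariate
ComBat/CovBat baselines, synthetic-data generators (model-concordant,
model-misspecified covariance mixtures, latent-space distortions) and a
full evaluation battery (ANOVA/Kruskal–Wallis/Levene/Bartlett/
Fligner–Killeen, MANOVA, Box's M, stratified 10-fold random-forest batch
AUC, four correlation-matrix distances, BH-controlled signal preservation,
EB prior checks, MCMC diagnostics) are included.

## Worked example

```r
library(mvharmonize)

cfg <- simConfig(n = 210, p = 15, M = 4)      # 3 batches, IW batch covariances
sim <- simulatePanel(cfg, seed = 3)
sim@observed
#> PanelData: 210 subjects x 15 features x 4 metrics
#> metrics: m01, m02, m03, m04
#> batches: site1(n=70), site2(n=70), site3(n=70)
#> covariates: age, sex, diagnosis

before <- multivariateBatchTests(sim@observed, ~ age + sex + diagnosis)
mean(before$boxm_p_bonf <= 0.05)              # fraction of features with
#> [1] 0.2                                    # covariance batch effects

h <- mvCombat(sim@observed, ~ age + sex + diagnosis)
h$posteriors
#> BatchPosteriors (eb): 3 batches x 15 features x 4 metrics
#> 45 of 45 fixed points converged

after <- multivariateBatchTests(h$data, ~ age + sex + diagnosis)
mean(after$boxm_p_bonf <= 0.05)
#> [1] 0
```

Box's M tests each feature's 4-dimensional residual vectors for equal
covariance across the three sites (Bonferroni over features): 20% of
features show batch-distorted cross-metric covariance before harmonization
and none after MV-ComBat, while the diagnosis/age/sex effects named in the
formula are preserved. `mvCovbat()` is called the same way and additionally
harmonizes the shared latent subspace; `uvCombat()`/`uvCovbat()` are the
univariate baselines; `rfBatchAUC(h$data, "m01")` measures residual global
batch signal in one metric. `readPanel()`/`writePanel()` move panels in and
out of long/wide CSV/TSV, and `inst/scripts/mvharmonize` exposes
`simulate`, `harmonize`, `evaluate` and `benchmark` subcommands for shell
use.

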