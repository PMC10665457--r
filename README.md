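# streakdecode

Tools for studying how motion direction can be represented as a **bimodal
probability distribution**. Fast motion leaves oriented "streaks" in the
visual input; streak orientation constrains the axis of motion but not its
sign. An observer who combines a velocity cue with this spatial-orientation
cue can therefore end up with a posterior over motion direction that has
peaks at both the true and the opposite direction — and so can a
probabilistic decoder reading out that posterior from voxel activity.

The package is aimed at computational and systems neuroscientists who want
to simulate, decode, and quantify such bimodal direction representations.

## What is implemented

**Bayesian observer.** Velocity measurements
$x_V \sim \mathrm{VM}(s, \kappa_V)$ and orientation measurements
$x_O = (s + \eta) \bmod 180°$, $\eta \sim \mathrm{VM}(0, \kappa_O)$. Under
a flat prior the posterior is an exact two-component von Mises mixture

$$p(s \mid x_V, x_O) = w_A\,f_{VM}(s;\theta_A,\kappa_A) +
  w_B\,f_{VM}(s;\theta_B,\kappa_B),$$

whose parameters follow from the product identity for von Mises densities
(`combined_posterior()`). Readouts: grid MAP (delta cost) and a
velocity-only observer. Seeded Monte-Carlo engines reproduce the model's
predictions over a noise ladder (`run_grid_simulation()`) and under an
fMRI-matched trial-wise noise regime with additional MRI measurement noise
(`run_decoded_simulation()`).

**Probabilistic voxel decoder.** Generative model $b = Wg(s) +
\varepsilon$ with $K = 8$ raised-cosine channels
$g_k(s)=\max(0,\cos(s-\varphi_k))^5$ and structured shrinkage noise
covariance $\Omega = \lambda\,\Omega_{\mathrm{sample}} +
(1-\lambda)\,[\sigma^2WW^T + (1-\rho)\,\mathrm{diag}(\tau^2) +
\rho\,\tau\tau^T]$; leave-one-run-out cross-validation with bagging
(`crossval_decode()`). Synthetic voxel datasets are generated from the same
model, optionally with a 180°-periodic orientation-code component
(`voxel_truth()`, `sample_voxel_patterns()`).

**Posterior shape analysis.** Descriptive two-von-Mises-plus-uniform fits
by Jensen–Shannon divergence minimization with random restarts
(`fit_descriptive_mixture()`), component disambiguation, bivariate von
Mises clustering of peak-location pairs compared by WAIC
(`cluster_peak_pairs()`), and peak-location/behavioral-error regressions.

**Behavioral analysis.** Cardinal-bias removal (attraction vs repulsion
polynomial models), ±3 SD outlier flagging, uncertainty–variability
regression with permutation inference, and the unimodal-vs-bimodal
response-distribution comparison by BIC (`fit_response_models()`).

## Worked example

```r
library(streakdecode)

# posterior for one trial with precise orientation but noisy velocity
post <- combined_posterior(list(x_V = 20, x_O = 5),
                           observer_params(sigma_V = 60, sigma_O = 10))
post
#> posterior mixture: w_A=0.938 at 5.6 deg (kappa 34.7); w_B=0.062 at 184.3 deg (kappa 32)

# high velocity noise: the across-trial mean posterior becomes bimodal
sim <- run_grid_simulation(sigma_V_values = 60, sigma_O_values = 10,
                           n_trials = 10000, seed = 1)
cl <- classify_mean_posterior(sim$cells[[1]]$mean_posterior, seed = 1)
cl$kind
#> [1] "bimodal"
round(c(mode = cl$mode, secondary = cl$secondary), 1)
#>      mode secondary
#>       0.0     180.2

# decode synthetic voxel data and benchmark recovery
ds <- sample_voxel_patterns(make_design(10, seed = 2),
                            voxel_truth(n_voxels = 200, seed = 1), seed = 3)
cv <- crossval_decode(ds, n_boot = 50, seed = 4)
cv
#> cross-validated decode: 180 trials, 10 runs; decoded-vs-true circular r = 0.714
```

The first call shows the two posterior components: most mass near the
(noisy) velocity measurement, but 6% of it at the opposite direction —
the orientation cue's unresolved 180° ambiguity. The grid simulation shows
that averaged over trials this produces a mean posterior with a secondary
peak at 180° when velocity noise is high. The decoder recovers synthetic
stimulus directions with a circular correlation of about 0.7 at the
default signal-to-noise level.

See `vignettes/bimodal-direction-posteriors.Rmd` for the models,
assumptions, parameter conventions, and design decisions.

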