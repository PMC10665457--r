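---
title: "Bimodal posterior representations of motion direction: models, decoding and shape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimodal posterior representations of motion direction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streakdecode)
```

## The scientific problem

A fast-moving dot field leaves oriented "streaks" in the visual input.
The streak orientation is informative about the *axis* of motion but not
its sign: a horizontal streak is equally consistent with leftward and
rightward motion. An observer who combines the velocity cue (which lives
in the full 360° direction space) with the spatial-orientation cue (which
lives in the 180° orientation space) therefore faces a built-in ambiguity.
This package implements the computational chain for studying the
consequence of that ambiguity: the posterior distribution over motion
direction can become *bimodal*, with peaks at the true and the opposite
direction, and that bimodality should be visible in probabilistic decodes
of visual-cortex activity and, under high stimulus uncertainty, in
behavior itself.

## The observer model

Measurements are von Mises perturbed: the velocity measurement
$x_V \sim \mathrm{VM}(s, \kappa_V)$ in direction space, and the
orientation measurement $x_O = (s + \eta) \bmod 180°$ with
$\eta \sim \mathrm{VM}(0, \kappa_O)$. Concentrations convert to circular
SDs through $\sigma = \sqrt{-2\log(I_1(\kappa)/I_0(\kappa))}$
(`kappa_to_sigma()` / `sigma_to_kappa()`).

Under a flat prior the posterior is proportional to
$\mathrm{VM}(s; x_V, \kappa_V)\,[\mathrm{VM}(s; x_O, \kappa_O)
+ \mathrm{VM}(s; x_O + 180°, \kappa_O)]$. Each product of two von Mises
densities is again von Mises (resultant-vector addition for the mean and
concentration, Bessel normalizers for the weight), so the posterior is an
*exact* two-component von Mises mixture (`combined_posterior()`). The
package derives the component parameters analytically and tests them
against brute-force normalization of the likelihood product on the grid
(sup-norm agreement better than $10^{-8}$). Component A is labeled as the
one nearer the velocity measurement so downstream analyses are
deterministic.

Readouts: the MAP readout locates the posterior maximum on a 0.5°-step
grid (ties broken toward the smaller canonical angle); the velocity-only
readout returns $x_V$ (the mode of the velocity-only posterior). In the
low-velocity-noise regime the MAP distribution across trials is
approximately von Mises with mean $s$ and concentration
$\kappa_O + \kappa_V$; `map_distribution_approx()` warns when the second
component's typical weight exceeds $10^{-3}$, where the approximation
degrades.

## Simulations and their conditions

`run_grid_simulation()` reproduces the model's predictions over the
standard noise ladder $\sigma_V, \sigma_O \in
\{3, 5, 10, 20, 30, 40, 60, 100\}°$ with 10,000 trials per cell, stimulus
fixed at 0° (the model is equivariant, so all results are relative
angles). Per cell it records the across-trial mean posterior, per-trial
MAP and velocity-only readouts, posterior entropies (in bits; see below),
and the weight and location of the posterior component lying within 90° of
the opposite direction.

**Bimodality of a mean posterior.** We deliberately do not count local
maxima: at $\sigma_V = 40°, \sigma_O = 30°$ the exact mean posterior has a
broad opposite-direction shoulder but no distinct local maximum, yet the
opposite-direction component carries about 11% of the posterior mass.
Instead a mean posterior is called bimodal when the across-trial mean
weight of the opposite-window component reaches 5% — the same threshold
below which a second component is treated as negligible elsewhere in the
package. On the ladder this classifies every $\sigma_V \le 30°$ cell
unimodal (largest weight 2.9%) and every $\sigma_V > 30°,
\sigma_O \le 30°$ cell bimodal (smallest weight 5.7%), with about twenty
Monte-Carlo standard errors of margin at 10,000 trials.

**The fMRI-matched regime.** `run_decoded_simulation()` draws trial-wise
neural precisions log-normally ($\mu = 3.8$, $\sigma = 0.6$ on the natural
log of $\kappa$; this reproduces behavioral variability of the right
magnitude, mean absolute error ≈ 5°) and corrupts the *decoded* (but not
the behavioral) measurements with independent MRI noise: von Mises offsets
added to each internal measurement, with the decoded concentration the sum
of neural and MRI precisions. The MRI noise magnitudes are drawn
log-normally with the parameters (0.9, 1.1) for velocity and (1.4, 0.7)
for orientation. The package interprets these draws as the MRI noise
*circular SD in degrees* and converts them to concentrations. The
alternative reading — log-normal draws of the concentration itself — puts
roughly a fifth of all trials at $\kappa' < 1$, i.e. near-uniform MRI
offsets; that would make the larger posterior component land near the
opposite direction on ~10% of trials and smear the joint peak-location
distribution, two orders of magnitude away from the tight three-cluster
structure (minority cluster a fraction of a percent) this regime is meant
to produce. Under the adopted reading the minority-cluster fraction is
about 0.1%, the right order of magnitude. `noise_regime(mri_param_space =
"log_kappa")` switches to the literal reading for comparison.

**Peak-error slopes.** The simulation-stage analysis
(`peak_error_correlation()`) regresses the behavioral error on each
sine-transformed peak location *separately*. The data-stage analysis
(`peak_error_regression()`) uses the joint two-predictor regression with
per-subject intercepts and permutation inference. The distinction matters:
a MAP reader's response tracks the decoded first peak almost exactly, so
in a joint model the second peak's shared signal is suppressed and its
partial slope can invert, while the marginal relationship keeps its sign
(MAP readout: both slopes positive; velocity-only readout: the second-peak
slope is negative because the second component is *repelled* from the
velocity measurement by the resultant geometry).

**Entropy units.** Entropies are reported in bits on the 720-bin grid.
Absolute entropy depends on the bin width, which is why only entropy
*orderings* and *differences* are ever asserted, never absolute values.

## The voxel decoder

The decoder is the generative-model approach in which voxel responses are
$b = W g(s) + \varepsilon$: each voxel's tuning is a nonnegative mixture
of $K = 8$ half-rectified raised-cosine channels
$g_k(s) = \max(0, \cos(s - \varphi_k))^5$, and the noise is multivariate
normal with the structured covariance
$\Omega_0 = \sigma^2 W W^T + (1-\rho)\,\mathrm{diag}(\tau^2) +
\rho\,\tau\tau^T$, shrunk toward the sample covariance by
$\Omega = \lambda\,\Omega_\mathrm{sample} + (1-\lambda)\,\Omega_0$ and
with per-voxel variances shrunk toward their median by $\lambda_{var}$.
Tuning weights are fit by ordinary least squares; $(\rho, \sigma^2)$ by
maximizing the Gaussian likelihood of the residuals with $\tau$ fixed at
the residual SDs (a moment-matching fallback exists). Decoding evaluates
the Gaussian likelihood of a test pattern at every grid direction in log
space with max-subtraction and normalizes under a flat prior; the decoded
direction is the posterior circular mean (the mode is also exposed, since
both conventions are in circulation) and uncertainty is the entropy.

Cross-validation is leave-one-run-out with bagging: training trials are
resampled with replacement, the model refit per resample, and the test
posteriors averaged (default 50 resamples; the number is configurable, as
no canonical value exists). Shrinkage weights are selected once per fold
by held-out likelihood on an inner 80/20 split of the training set over a
small grid in $[0,1]^2$, rather than per bootstrap resample — the selected
weights are stable across resamples and per-fold selection costs 500× less.
This is a reimplementation choice; the reference decoder ties the
selection to its own bootstrap machinery.

## Synthetic data

`voxel_truth()` + `sample_voxel_patterns()` generate datasets from exactly
the decoder's generative assumptions: random nonnegative channel mixtures
per voxel (the field has no quantitative account of real voxel tuning
heterogeneity, so smooth random mixtures are the neutral choice), an
optional 180°-periodic "orientation code" built from equal-weight pairs of
opposite-preferring channels (mixing weight `ori_weight`), and structured
noise of the $\Omega_0$ form. The default size is 10 runs × 18 trials and
200 voxels; the default amplitude (1.5) was set so that leave-one-run-out
decoding of a pure-direction dataset attains a decoded-vs-true circular
correlation of about 0.7, the magnitude reported for real recordings.
Designs follow the standard estimation layout: 18 evenly spaced directions
per run with a uniform random offset, shuffled within run. Within-run
z-scoring is applied across the run's trial patterns; no time dimension is
simulated, which is the one respect in which the normalization differs
from its BOLD counterpart.

`make_behavioral_dataset()` adds the statistical structure the behavioral
analyses assume: cue SDs scaled linearly with distance to the nearest
cardinal direction (oblique effect), an additive fourth-harmonic cardinal
bias ($b\,\sin 4s$; positive = repulsion), and a uniform lapse component.

What passing tests on these data do *not* show: robustness to hemodynamic
time-course structure, voxel selection, spatial noise correlations beyond
the $\Omega_0$ form, or realistic tuning heterogeneity — synthetic
defaults exercise the pipeline, they do not certify it for real data.

## Posterior shape analysis

`fit_descriptive_mixture()` fits the descriptive model — two von Mises
components plus a circular uniform — to a posterior by minimizing the
Jensen–Shannon divergence (base 2) on the grid, with bounded L-BFGS-B from
100 random starts plus one data-driven start (the posterior's main peak
and the highest point of the opposite half-circle). Bounds:
$\kappa \in [0.001, 100]$, $\alpha \in [10^{-5}, 1-10^{-5}]$,
$\lambda \in [0, 0.9]$. Restart dispersion (circular SD of component
locations across solutions with JSD within 5% of the best) flags
unidentifiable fits such as near-uniform posteriors. Components are
disambiguated both by height (mixture density at the component means;
proximity breaks exact ties) and by proximity to the true direction.

`cluster_peak_pairs()` models the joint distribution of per-trial peak
locations as a mixture of independent-coordinate bivariate von Mises
clusters (the within-cluster independence is an assumption; nothing in
the analyses requires within-cluster angular covariance). Candidate
cluster counts are compared by WAIC computed from pointwise
log-likelihoods over posterior draws of a random-walk Metropolis sampler
initialized at the EM solution (two chains; acceptance adapted to ~25%
during burn-in; split-Rhat of the log-likelihood trace reported and the
fit flagged above 1.1). A deterministic EM + BIC comparison is available
as a fast fallback; WAIC is the reference method. Because the mixture
likelihood is label-invariant, label switching does not affect WAIC.

The cluster-count contrast between dual-code and pure-direction synthetic
data is an experiment about the *code*, so it is run in a
high-signal-to-noise configuration (amplitude 2.5, decoded-vs-true
correlation ≈ 0.97): at lower SNR a second cluster starts absorbing
broad, noise-dominated posteriors whose smaller component scatters over
the circle, and the comparison stops being about the presence of an
orientation code. At matched SNR the dual-code data always yield a higher
fraction of opposite-direction components than pure-direction data.

## Behavioral analysis

Cardinal-bias removal fits two candidate models — attraction (bins
centered on cardinals) and repulsion (bins centered on obliques) — each
with a 4th-degree orthogonal polynomial for the mean error per 90° bin,
computed relative to the bin center to avoid circular discontinuities at
bin edges. Dispersion is modeled as log-variance linear in distance to the
bin center, fit in two stages (OLS mean, then a bias-corrected
log-residual regression); the functional form is a package choice since
only the sign and shape of the oblique effect are testable. The
better-likelihood model is selected per subject; residuals beyond 3
predicted SDs are flagged as outliers.

The follow-up-experiment comparison (`fit_response_models()`) fits, by
multi-start bounded maximum likelihood, a unimodal von Mises plus lapse
versus a two-component mixture with peaks fixed at 0° and 180° plus
lapse, and compares BIC per subject (group inference by summing BIC
differences — exactly the printed group rule; no random-effects model
selection). The deterministic start grid replaces a global evolutionary
optimizer; with 2–4 bounded parameters the start grid reliably reaches
the global optimum (verified by parameter recovery on simulated data).

## Numerical choices

* Degrees at every public interface, radians internally.
* von Mises densities in log space with exponentially scaled Bessel
  functions; for $\kappa > 10^4$ the Bessel ratio and $\log I_0$ switch to
  asymptotic expansions (base R's `besselI` underflows near $7\times10^5$).
* The circular correlation is the Fisher–Lee pairwise-difference
  coefficient via an $O(n)$ identity — mean-centered variants have an
  arbitrary sign when the marginals are uniform, which is exactly the
  situation for decoded directions spanning the circle.
* Argmax ties break toward the smaller canonical angle; grid bins are
  centered at $0, 0.5, \dots$ (bin alignment is a convention; nothing
  downstream depends on it).
* Posterior grids: 720 bins of 0.5°. Covariance fits add a diagonal
  jitter (recorded in the fit) only if the shrunk covariance loses
  positive definiteness.

## Problem sizes used by the test suite

The acceptance-style checks run the grid simulation at the full printed
size (64 cells × 10,000 trials, ≈ 1 minute), the fMRI-matched simulation
at 10,000 trials, decoder recovery at 200 voxels / 10 runs / 50 bootstrap
resamples, and the end-to-end shape pipeline at 10 runs with 10 resamples
and 8 restarts per trial fit. Unit tests use smaller sizes chosen so each
statistical assertion retains several standard errors of margin.

## What entropy does and does not track

Across the noise ladder, combining the orientation cue always lowers mean
posterior entropy relative to the velocity-only observer, and entropy
broadly tracks response variability (rank correlation ≈ 0.86 across the
64 cells). The relationship is not perfectly monotone, and cannot be: a
cell with very noisy velocity but precise orientation (say
$\sigma_V = 100°, \sigma_O = 3°$) yields a *sharply bimodal* posterior —
two narrow peaks, hence low entropy (~5.6 bits) — while the MAP response
flips between the true and opposite direction across trials, making the
response circular SD near its maximum. Once posteriors go bimodal,
entropy stops being a proxy for response variability; treat the two as
distinct summaries.

A related degeneracy affects cluster-count comparisons on synthetic
decodes: pure-direction datasets produce near-exact von Mises posteriors,
so the descriptive fit's smaller component is unidentifiable on most
trials, and whatever convention one adopts for those trials introduces a
second population of peak pairs that information criteria duly detect.
The presence of an orientation code is therefore best read from the
*location* of the fitted clusters (is there a cluster at the opposite
direction, and how much weight does it carry?) rather than from the raw
preferred cluster count.

## Known limitations

* The MRI-noise parameterization is reconstructed from internal
  consistency (see the simulation section); both readings are available.
* Shrinkage-weight selection differs in detail from the reference
  decoder's procedure (held-out-likelihood grid per fold).
* The hierarchical Bayesian regressions of the original analyses are
  replaced by fixed-slope regressions with per-subject intercepts and
  permutation inference throughout.
* WAIC is computed from a short random-walk chain; for publication-grade
  cluster inference one would run a longer sampler and check Rhat per
  parameter, not only on the log-likelihood trace.
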