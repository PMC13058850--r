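---
title: "Grid-like signal analysis: model, simulation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-like signal analysis: model, simulation, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Entorhinal grid cells fire on a hexagonal lattice, and their population
activity is conjectured to leave a macroscopic trace in fMRI: BOLD
amplitude during movement modulated with 60-degree (6-fold) periodicity in
the allocentric movement direction $\phi$. `gridls` implements the standard
two-stage, split-half estimate of this *grid-like signal* (GLS).

**Stage 1 (estimation).** On the first half of a run, every voxel $v$ is fit
with a GLM whose regressors of interest are the translation-event boxcars
parametrically modulated by $\sin(k\phi)$ and $\cos(k\phi)$ (fold $k = 6$
for the grid signature), convolved with a canonical double-gamma HRF. The
quadrature coefficients $(\beta_1, \beta_2)$ give

$$\theta_v = \frac{1}{k}\,\operatorname{atan2}(\beta_1, \beta_2), \qquad
  a_v = \sqrt{\beta_1^2 + \beta_2^2},$$

the voxel's preferred orientation (on the fundamental domain
$[0^\circ, 360^\circ/k)$) and its modulation amplitude. The printed formula
$\arctan(\beta_1/\beta_2)/k$ is implemented with the two-argument
arctangent: plain `atan` would fold half of the domain onto the other half.
The ROI summary is the amplitude-weighted circular mean

$$\bar\varphi = \frac{1}{k}\,\operatorname{atan2}\!\Big(\sum_v a_v \sin k\theta_v,\;
  \sum_v a_v \cos k\theta_v\Big),$$

with the resultant length reported as a dispersion diagnostic. Voxels with
$\beta_1 = \beta_2 = 0$ have no orientation and are excluded rather than
contributing an arbitrary angle; a resultant below tolerance (perfectly
dispersed orientations, e.g. two antipodal voxels) is an error, not a
number.

**Stage 2 (test).** On the held-out second half, a single parametric
modulator $\cos\!\big(k(\phi - \bar\varphi)\big)$ scores how well held-out
activity aligns with the estimated orientation. Its coefficient, averaged
over ROI voxels (unweighted — the voxel-wise fit preserves per-voxel
diagnostics), is the cross-validated GLS magnitude: positive when
orientations persist across halves, zero in expectation when they do not.
The analysis runs separately per hemisphere, run and fold; participant
values are plain arithmetic means across runs, falling back to the
available run (with a logged flag) when a cell fails.

Fold symmetries $k \in \{5, 7\}$ serve as specificity controls and $k = 1$
as a head-direction proxy, all through the identical two-stage machinery.

## Design matrices

Every design contains: intercept; unmodulated translation boxcar (the
modulators are not orthogonalised against it — balanced directions make
them near-zero-mean by construction); the modulator(s); an unmodulated
rotation boxcar as nuisance (the source design does not dictate this; we
model rotations rather than leave them as unmodelled baseline); and a drift
set. Event regressors are boxcars on a 0.1 s microtime grid, convolved with
the HRF (double gamma, response shape 6 s, undershoot 16 s, ratio 6:1,
32 s support, unit peak, no derivatives), then sampled at scan onsets.

Two numerical choices deserve note:

* **Drift set = linear trend + discrete-cosine basis (128 s cutoff).** A
  truncated cosine set alone absorbs a linear trend only approximately; with
  the explicit linear column, adding any linear trend to the data leaves the
  quadrature betas unchanged to machine precision, which turns "drift
  immunity" from an approximation into an identity that the tests assert at
  `1e-6`.
* **Cross-boundary carry-over.** The hemodynamic tail of estimation-half
  events bleeds roughly 30 s into the test half. The test design therefore
  includes nuisance columns holding the convolved tails of the pre-boundary
  events (their boxcar, quadrature, and rotation components, re-clocked with
  negative onsets). Without them, noiseless planted runs are recovered only
  to ~2e-3; with them, recovery is exact. An event straddling the split
  boundary is truncated at the boundary and kept in the estimation half, as
  is conventional.

Estimation is voxel-wise OLS without prewhitening: no whitening scheme is
prescribed for the original analyses, and under the simulator's AR(1) noise
unwhitened OLS remains unbiased — autocorrelation only inflates coefficient
variance, which the calibration properties absorb.

## The synthetic task and BOLD generator

Because the motivating datasets are access-restricted, validation rests on
a generator that reproduces the *published design parameters* of the
passive navigation task:

| parameter | default | source/rationale |
|---|---|---|
| room | 160 × 160 vm | published design |
| speeds | 15 vm/s translation, 50°/s rotation | published design |
| run length | 620 s | published design |
| segments | 112, balanced over 36 × 10° bins (3–4 each) | published design |
| rotation magnitude | shortest arc in [10°, 170°] | published design |
| segment length | uniform on [32, 76] vm, wall-clamped | chosen so the realised mean is ≈ 50 vm, matching the published realised means |
| coverage geometry | 3 vm disc + 8 vm cone, 65° *full* width | published design; full-width reading of the ambiguous "65 degree width" |

Directions are drawn uniformly *inside* their 10° bin (bin centres would
produce comb artifacts), ordered by a randomised greedy walk that enforces
the turn-magnitude constraint (exact 180° reversals are impossible, which
is what makes the printed 170° maximum attainable) and keeps the path
inside the room; a trailing stationary *rest* event pads the schedule to
exactly 620 s and is logged explicitly so models can include or ignore it.
Coverage rasterises the room into 1 × 1 vm bins and samples the path at
0.5 vm steps (< half the bin size, to avoid step aliasing); positions use a
corner origin, x rightward, y upward, 0° = +x, counterclockwise positive.
Realised totals (path length ≈ 5.3–5.7 km, coverage ≈ 75–80%) fall in the
published range, though realised-length statistics are design outputs, not
calibrated quantities.

The BOLD model plants a known signal: voxel orientations $\theta_v$ drawn
von Mises around a group orientation $\theta^*$ with concentration $\kappa$
*in k-fold angle space* ($\kappa = 0$: uniform; $\kappa \to \infty$: all
voxels at $\theta^*$); neural activity
$a_v \cos\!\big(k(\phi - \theta_v)\big)$ as a boxcar over each translation;
HRF convolution through the same code path as the analysis designs; plus
baseline, linear drift, and stationary AR(1) Gaussian noise (marginal SD =
`noise_sd`). An optional orientation drift at the run midpoint destabilises
the signal for temporal-stability experiments. With zero noise the planted
series is, by the identity
$\cos(k\phi - k\theta) = \cos k\theta \cos k\phi + \sin k\theta \sin k\phi$,
an exact linear combination of the fold-k quadrature regressors — the
anchor for the exact-recovery tests.

What the generator does *not* emulate: spatial autocorrelation between
voxels, physiological (cardiac/respiratory) noise structure, head motion,
susceptibility dropout, multi-echo acquisition, or behavioural variation.
Passing tests therefore certify the *estimator chain*, not robustness to
every artefact of real entorhinal fMRI.

## Stability and quality control

*Temporal stability* is the fraction of voxels whose orientations from the
two halves agree within ±15° in the fold's periodic space; its chance level
is $2 \cdot 15 / (360/k) = 50\%$ for $k = 6$. The tolerance generalises as
$(360/k)/4$ but defaults match the 6-fold usage. Voxels with an undefined
orientation in either half leave the denominator, with counts logged.
*Spatial stability* maps orientations to $k\theta_v$ and applies Rayleigh's
test, $Z = n\bar R^2$, with the standard small-sample series approximation
for $p$, clipped to $(0, 1]$; voxels are unweighted (amplitude weighting is
not indicated for this step). *tSNR screening* excludes voxels whose
temporal mean/SD falls more than 1.5 IQR below the first quartile
(type-7 linear-interpolation quartiles — the convention is not specified in
the source, so R's default is used); constant series are excluded outright.

## Group statistics

One-sample and Welch tests default to one-sided upper-tail $p$ — the
direction pinned by the printed pairs (t = 2.383 → p = 0.009;
t = −0.443 → p = 0.671) — with `alternative` exposed. Cohen's d is
$t/\sqrt{n}$ (one-sample) or the pooled-SD difference (two-sample). JZS
Bayes factors are two-sided with a Cauchy prior of width
$r = \sqrt{2}/2$ (the value "0.707" abbreviates), computed by numerical
integration of the Rouder marginal-likelihood ratio; the two-sample BF uses
the pooled t with effective sample size $n_1 n_2/(n_1+n_2)$ even though the
frequentist test is Welch, mirroring common tooling (a deliberate,
documented mismatch). Bonferroni families divide 0.05 by family size
(primary 6-fold family of 2 → 0.025; 5-/7-fold control family of 4 →
0.0125). Pearson correlations carry Fisher-z intervals, clipped at ±1 for
degenerate samples. Linear mixed-effects models are deliberately out of
scope: the pipeline emits tidy long-format tables ready for any standard
mixed-model tool.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles (dense grid
searches for orientations and circular means, normal-equation solvers for
the GLM, hand-expanded quartiles, closed-form Welch df and Fisher-z
intervals, and a noncentral-t quadrature for the Bayes factor), then
exercises the full pipeline at these scales, chosen to give statistical
headroom at desk-scale runtimes:

* exact recovery: noiseless 620 s runs, 4–5 voxels, tolerance 1e-6;
* parameter recovery: 100 participants, 20 voxels, $\kappa = 8$, amplitude
  0.5, noise SD 1, one shared default trajectory — median orientation error
  well under 5° in 60°-space;
* null calibration: 500 cohorts of 50 participants, 8 voxels, amplitude 0 —
  one-sided type-I error, Rayleigh rejection rate, and temporal stability
  at their nominal 5%/5%/50%;
* chance-level stability: $10^5$ independent uniform orientation pairs.

## Known limitations

**Cross-fold leakage on a fixed trajectory.** On a single shared path, the
convolved $\cos(6\phi)$ and $\cos(7\phi)$ (or $\cos\phi$) regressor sets
are not orthogonal over ~56 events per half, and the serial structure of
directions (bounded turns, no reversals) strengthens the coupling. A strong
planted 6-fold signal then leaks a *deterministic, trajectory-specific*
mean into control-fold magnitudes (noiseless probes: ≈ +0.01 to −0.05
signal units for amplitude 0.5, either sign depending on the path). Because
every participant shares the trajectory, this bias does not average out
across a cohort — a caution directly relevant to interpreting unexpected
control-fold findings in shared-trajectory designs, and the reason the
7-fold "mean within 2 SE of 0" check fails on the default path while the
5-fold check passes. Varying trajectories across participants (not part of
the emulated design, where paths are fixed per run) would remove it.

**Other limits.** The Rayleigh $p$ series approximation degrades for
$Z \approx n$ at very small $n$ (values are clipped into $(0,1]$); OLS
without prewhitening is inefficient (not biased) under heavy
autocorrelation; the GLM2 ROI summary is a voxel-mean coefficient, not a
coefficient of the ROI-mean series (the source wording is ambiguous; the
voxel-mean preserves diagnostics); and the generator's independence across
voxels makes spatial-stability findings on synthetic data optimistic
relative to spatially smooth real noise.
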