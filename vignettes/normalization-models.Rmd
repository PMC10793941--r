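---
title: "Normalization models of visual-cortex responses to band-pass textures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization models of visual-cortex responses to band-pass textures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Population fMRI responses in human V1–V3 are substantially larger for
*snakes* (curved band-pass contours) than for *gratings* (straight parallel
contours), even when the two classes carry the same total contrast energy. A
model that pools contrast energy over space and orientation — with or without
an untuned divisive gain control — cannot produce this difference, because
both stimulus classes drive the pooled energy equally. The difference is
captured once the normalization signal is made sensitive to how energy is
*distributed across orientations*: either through an orientation-tuned
surround, or through the anisotropy of the orientation-channel outputs.

`visnorm` implements this model family end to end: stimulus synthesis,
oriented contrast energy, four pooling models, least-squares fitting with
leave-one-out cross-validation, and the diagnostic experiments that separate
the models.

## The model family

All four models share three stages.

**1. Oriented contrast energy.** The preprocessed image $I(x, y)$ (zero mean,
range $[-0.5, 0.5]$, gray surround) is projected onto 128 Gabor filters: 8
orientations every 22.5°, 8 peak frequencies log-spaced from 0.75 to
6 cycles/deg, and 2 phases in quadrature. Each filter is a cosine or sine
carrier of 4 cycles under an isotropic Gaussian window with SD of one cycle,
realized on a square support of 4 wavelengths and mean-subtracted so that a
uniform gray field yields zero energy. Before filtering, the image is padded
with gray by the width of the largest filter; outputs are squared, summed
over the two phases (phase invariance) and over the 8 frequency bands
(uniform weights), and downsampled to 12 px/deg by area-weighted block
averaging:

$$E(x, y, \theta) = \sum_{\phi, f}
  \Big(\sum_{x', y'} I(x - x', y - y')\, F(x', y', \theta, f, \phi)\Big)^2 .$$

This stage has no free parameters.

**2. A pooling functional** $s = \Phi[E]$, the only stage that differs
between models:

* **CE (contrast energy).** $s$ is the mean of $E$ over space and
  orientation. No parameters.
* **DN (untuned divisive normalization).** Each sample is divided by a
  pooled neighborhood before averaging: $d = E / (\sigma + Z)$ with
  $Z$ the spatial Gaussian convolution of the orientation-summed energy.
  The Gaussian SD is 4% of the padded image width (about 1 deg); each
  orientation plane of the pool sums to 1 and all 8 planes contribute, so a
  uniform field $E = c$ gives $Z = 8c$. One parameter, $\sigma$.
* **OTN (orientation-tuned normalization).** As DN, but the pool at
  *surrounding* positions is restricted to the same orientation channel,
  while *other* orientations contribute only at the center pixel
  (cross-orientation suppression). One parameter, $\sigma$.
* **NOA (normalization by orientation anisotropy).** The energy is first
  summed over space within each orientation band, $e(\theta)$, then
  normalized by the anisotropy of that 8-vector:
  $s = \frac{1}{8}\sum_\theta e(\theta)^2 \big/ (\sigma^2 + V)$ with
  $V = \sum_\theta (e(\theta) - \bar e)^2$. Numerator and $\sigma$ are
  squared to keep parameter scales comparable across models;
  `pool_noa(variant = "sqrt")` exposes the unsquared form
  $\bar e / (\sigma + \sqrt V)$, whose large-$\sigma$ limit coincides
  exactly with CE.

**3. A power law** $r = g\, s^{\alpha}$ mapping the pooled drive to BOLD
percent signal change, with gain $g \ge 0$ and exponent
$\alpha \in (0, 1)$ (compressive). CE has 2 free parameters; DN, OTN and NOA
have 3.

### The tuned pool's cross-orientation weight

The orientation-tuned pool is a weight matrix over (relative position,
orientation pair): wide Gaussians on the diagonal (same orientation), narrow
one-pixel kernels off the diagonal. We match the off-diagonal kernels to the
diagonal Gaussian **in amplitude**, not in integral: the cross-orientation
weight per unit energy equals the peak of the unit-sum surround Gaussian
(about $1/2\pi\,\mathrm{sd}_{px}^2$). Had the one-pixel kernels carried unit
sum, every orientation would contribute the same total weight and the tuned
pool would be numerically indistinguishable from the untuned pool for any
spatially homogeneous texture — abolishing exactly the behavior the model
exists to produce. With amplitude matching, a grating (energy concentrated
in one channel, spatially extended) recruits a large same-orientation
surround pool, while a snake (energy scattered across channels) recruits
little, and the predicted snakes:gratings ratio lands near 2 at mid-range
$\sigma$.

## Stimulus synthesis

All families are band-pass limited near 3 cycles/deg by a zero-mean
isotropic difference-of-Gaussians filter whose discrete amplitude spectrum
peaks at 3 cycles/deg and crosses half-maximum at 1.4 and 4.7 cycles/deg
(each within the 10% contract). The requested band is marginally narrower
than a strict DoG admits — the Laplacian-of-Gaussian limit is the bandwidth
infimum of the family — so the solver works on the discrete spectrum with a
surround/center ratio floor of 1.02 and lands within a few percent of all
three targets.

Conventions shared by every family: contrast $c$ scales the pattern so the
extreme pixel is $c/2$ ($c = 1$ fills the full range; for sinusoids this
coincides with Michelson contrast); a half-cosine ramp blends the outer
0.5 deg of the circular aperture into the gray background; orientation 0°
means horizontal contours, increasing counterclockwise; one integer seed
fully determines a set, with exemplar $i$ drawn from `seed + i - 1`.

* **Snakes**: white noise low-passed at a cutoff (0.5 cycles/deg by
  default; density ladder 2.8/1.6/0.9/0.5/0.3), thresholded at its median,
  level crossings marked by first-difference filters in x and y combined by
  maximum, polarity inverted so edges are dark, then band-pass filtered.
  The threshold level and edge operator are unstated in the source
  description; the median threshold (guaranteeing balanced regions) and
  first differences are our choices.
* **Gratings**: one-pixel lines every `spacing_deg` (density ladder
  3/2.5/1.75/1/0.33 deg) convolved with the band-pass kernel, or 3 cycle/deg
  sinusoids whose nine exemplars step through equally spaced phases.
* **Waves**: snakes passed through a Fourier-plane angular Gaussian window
  (SD 20°, both half-planes) centered on the target orientation.
* **Noise bars**: parallel raised-cosine bands (full width 1/3 deg, the
  band-pass wavelength, clipped to half the spacing) multiplied into
  isotropic band-pass noise.
* **Plaid / circular**: sums of 2 or 16 equally spaced 3 cycle/deg sinusoids
  with random phases, rescaled so the pre-aperture RMS matches the
  sinusoidal grating set at the same contrast.
* **Cross gratings**: line gratings interrupted by periodic perpendicular
  blanks (25% or 50% duty cycle); excluded from the default batteries.

`make_target_battery()` builds the energy-matched snakes/gratings pair used
by the diagnostic experiments: within each contrast level, the class with
more total contrast energy is scaled down by the square root of the energy
ratio, making the match exact (energy is quadratic in pixel contrast); the
achieved ratios are reported in the battery's `energy_match` table.

### What the generator does and does not emulate

The generator reproduces the *texture statistics* that drive the models —
band-pass spectra, contour curvature versus straightness, orientation
content, contrast and density ladders — and a synthetic-BOLD generator adds
seeded Gaussian noise to model predictions for recovery tests. It does not
reproduce the published stimulus image files pixel for pixel, display gamma,
retinotopic inhomogeneity, voxel sampling, or the bootstrap structure of GLM
beta estimates. Tests that pass on these fixtures therefore validate the
model computations and their dissociations, not the specific variance
explained on any empirical data set.

## Fitting and cross-validation

Parameters are estimated by unweighted least squares on per-stimulus
responses (the prediction for a multi-exemplar stimulus is the mean across
exemplars). The search is unconstrained: $\alpha$ passes through a sigmoid
to $(0, 1)$ and $\sigma$ through an exponential; the gain is profiled out in
closed form at every objective evaluation ($g^* = \max(0, \sum q r / \sum
q^2)$ with $q_i = \overline{s_i^\alpha}$), which is the exact least-squares
optimum and removes the scale pathology of searching $g$ numerically. BFGS
with analytic gradients runs from 40 random initializations (standard normal
with SD 2 in transformed space, deterministic given the seed); the lowest
SSE wins, ties breaking toward the earliest start. Leave-one-out
cross-validation refits the model once per held-out stimulus and scores
predictions with $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, which is negative
whenever the model predicts worse than the data mean and is never clipped.

Two numerical choices matter for speed. Filtering is hoisted out of the fit:
for DN/OTN the pool $Z$ does not depend on $\sigma$, so each exemplar
caches its $(E, Z)$ pairs; zero-energy pixels are dropped (they contribute
nothing at any $\sigma$) and the rest are compressed into 512 Z-quantile
bins with energy-weighted bin centers. The exact pooling functions
(`pool_dn`, `pool_otn`) never use this compression; it exists only inside
`pooling_context()` for the fit loop. Denominators are floored at $10^{-12}$
to guard $\sigma = 0$ on empty pixels.

### Identifiability at desk scale

On the frozen 30-stimulus recovery battery (the dataset-1 design: the
3/10/25/50/100% contrast ladder for snakes, line gratings, waves and noise
bars, plus both density ladders at 25% contrast; truth $g = 1$,
$\alpha = 0.5$, $\sigma$ at the geometric-mean normalizer), with Gaussian
noise at 10% of the response range, $\alpha$ and $\sigma$ recover well in
median but the gain does not reach 10% median relative error. The reason is
structural: pooled drives sit several natural-log units below 1, so the fit
pivots at $\hat g \approx g\, s_{\mathrm{pivot}}^{\,\alpha - \hat\alpha}$
and any error in $\alpha$ is amplified into $g$ by $|\log s|$; the
Cramér–Rao bound at these exact conditions already sits near 10% for an
efficient estimator. The test suite asserts the 10% bound anyway and
documents the failure rather than relaxing it. Two further recovery
statistics are seed-marginal rather than structural: the median relative
error of $\sigma$ hovers at its 20% bound, and the held-out $R^2$ of the
generating model itself has expectation
$1 - \sigma_n^2/\mathrm{var}(r) \approx 0.9$ at this noise level, so single
replicates land on either side of 0.9.

## The diagnostic experiments

* **Snakes/gratings ratio** (`run_ratio_experiment`): model predictions
  averaged within class on the energy-matched battery; reported as
  mean(snakes)/mean(gratings). Default parameters $g = 1$, $\alpha = 1$ and
  a mid-range $\sigma$ (`suggest_sigma`: the energy-weighted geometric mean
  of the normalizer) make the ratio a property of the pooling functional
  alone.
* **Contrast slope** (`contrast_gap_experiment`): the snake-minus-grating
  prediction gap along the contrast ladder. Orientation-sensitive models
  predict a gap that grows with contrast (normalization bites only once the
  pooled energy is high, and bites gratings harder); untuned models predict
  a near-constant, near-zero gap on energy-matched stimuli.
* **Center–surround suppression** (`simulate_center_surround`): composite
  static 3 cycle/deg gratings — a 1 deg-radius center disc and a 1–3 deg
  annulus with hard edges — read out by a single unit at the image center
  preferring 0°. The unit's feedforward drive comes from the center-only
  stimulus (its classical receptive field; the surround lies outside it),
  while the normalization signal is computed on the composite. This
  separation is essential at this filter scale: the 0.75 cycle/deg Gabor
  spans over 5 deg, so surround energy otherwise leaks into the numerator
  and masks the suppression. With it, OTN's greatest suppression always
  sits at the unit's *preferred* direction, while NOA's follows the *center
  stimulus* direction — the dissociation between the two
  orientation-sensitive schemes.

## Problem sizes

The experiment batteries run at an 8-deg canvas and 12 px/deg (the energy
resolution, so no downsampling step), with 3 exemplars per stimulus for the
ratio/slope experiments and 1 for recovery studies; display-faithful
geometries (12.5 deg/400 px, 18.75 deg/600 px, 12.5 deg/256 px) are
available through `canvas_dialect()` and the config `dialect` field. These
sizes were chosen so the full suite — including 20 recovery replicates at 40
optimizer starts and a four-model leave-one-out comparison — completes on a
single CPU in minutes while preserving several contour periods of the
sparsest patterns inside the aperture.

## Known limitations

* Single-stage normalization plus an output power law; no cascaded or
  gated normalization, no second-order-contrast channel.
* No spatial receptive-field parameters: the models predict ROI-mean
  responses, not voxelwise maps, and carry no eccentricity-dependent
  frequency tuning.
* The padded-canvas pixel counts differ from the original display
  processing (whose padding/rounding details are not fully recoverable), so
  absolute $s$ and fitted $\sigma$ values are comparable within this
  package, not across implementations.
* `load_roi_betas()` delegates MAT parsing to a bundled Python helper
  (scipy/h5py); real-data runs additionally require downloading the public
  beta files, and no published variance-explained value is asserted without
  them.
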