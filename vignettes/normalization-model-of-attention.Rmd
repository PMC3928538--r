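---
title: "Attention effects on contrast-response in single neurons and populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention effects on contrast-response in single neurons and populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnorm)
library(dplyr)
```

attnorm simulates the normalization model of attention (Reynolds & Heeger,
2009) for a population of model neurons with heterogeneous spatial and
orientation tuning, classifies how attention changes contrast-response
functions, and implements the population-imaging analysis chain used to
measure the spatial extent of the attention field relative to the
stimulus-drive in visual cortex. This vignette documents the model, the
estimators, the tunable parameters, and the design choices taken where the
problem was genuinely open.

## The model

Each model neuron is indexed by the center of its receptive field $x$
(degrees of visual angle on a 1-D axis; the analyses collapse to radial
eccentricity) and its preferred orientation $\theta$ on $[-90^\circ,
90^\circ)$. Its response is the attention-modulated stimulus-drive divided
by a pooled suppressive drive:

$$R(x,\theta) \;=\; \max\!\Big(0,\;
  \frac{g(x,\theta)\,\big(E(x,\theta) + b\big)}
       {S(x,\theta) + \sigma} - T\Big)$$

* **Stimulus-drive** $E(x,\theta)$: each grating contributes its contrast
  (percent) times a Gaussian orientation-tuning factor (SD
  `e_theta_sd = 60`°, evaluated on circular distance with period 180°;
  the tuning width is the half-width at 60.7% of maximum, which for a
  Gaussian equals its SD) times its rectangular spatial envelope smoothed
  by the receptive-field Gaussian (SD `e_space_sd = 0.75`°, a published
  population receptive-field size for V1 at parafoveal eccentricity). The
  envelope shape is not uniquely determined by a grating's nominal size; a
  rectangular window of the stated full-width (default 6°) convolved with
  the RF Gaussian is used.
* **Modifiable baseline** $b$ (`baseline_mod`, default `5e-7` percent
  contrast): a contrast-equivalent input present regardless of the
  stimulus, added to $E$ *before* the attention gain so that attention can
  modulate activity even at zero contrast.
* **Attention gain** $g(x,\theta) = 1 + (g_{peak}-1)\,
  e^{-(x-x_0)^2/2w^2}$, with $w$ = `ratio` times the spatial size of the
  stimulus-drive. Size is defined operationally as the SD of a Gaussian
  fitted to the spatial profile of $E$ — the same definition used on the
  cortical side, where the attention-field/stimulus-drive size ratio of
  1.4 was estimated as the ratio of fitted cue- and contrast-sensitivity
  profile SDs. In `spatial_and_feature` mode the bump is further scaled by
  a Gaussian in orientation distance from the attended feature
  (`feature_sd` defaults to the excitatory tuning width, 60°; no
  independent estimate of the featural attention width was available).
* **Suppressive drive** $S$: the attention-modulated drive pooled
  uniformly over all orientations and over space with a Gaussian kernel of
  SD `s_space_sd = 20`° (taken literally in degrees of visual angle).
  Crucially the pool is built from the *modulated* drive, so neurons whose
  gain was raised by attention suppress their neighbors more.
* $\sigma$ (`sigma`): the semisaturation constant, which sets the
  horizontal position of the contrast-response function. The original
  model descriptions defer this to figure settings without printing a
  value; the default `sigma = 3` (percent-contrast drive units) places the
  well-tuned neuron's unattended $C_{50}$ near 19%, comfortably inside the
  default contrast ladder, so saturation is visible over the simulated
  range. `attention_peak_gain = 4` similarly follows common usage in this
  model family; both are plain configuration fields.
* **Spiking threshold** $T$ (`spike_threshold`, default 0): responses are
  half-wave rectified after subtracting $T$.

Numerical grid: space $[-15, 15]$° in 0.1° steps (resolving the 0.75° RF
and covering the attention field at the largest swept ratio), orientation
$[-90, 90)$° in 3° steps. The discrete suppressive kernel is renormalized
at each position to unit mass over the simulated window, so a spatially
uniform drive is pooled to exactly itself and no spurious edge attenuation
enters; the trade-off is that strict mean conservation holds only for
kernels well inside the window.

A population-scale (imaging-like) signal is the unweighted mean response
over every neuron on the grid; the "well-tuned neuron" is the grid node
nearest the stimulus center and orientation. The unattended condition sets
$g \equiv 1$ (attention absent), not attention directed elsewhere;
attend-away configurations are out of scope (see Limitations).

## Classifying attention effects

Attended/unattended contrast-response pairs are fit jointly with the
Naka-Rushton equation

$$R(C) = R_{max}\frac{C^n}{C^n + C_{50}^n} + R_{offset}$$

under three hypotheses, each freeing exactly one parameter in the attended
condition: $R_{max}$ (response-gain), $C_{50}$ (contrast-gain) or
$R_{offset}$ (additive-offset). The fit minimizes the unweighted summed
squared error of both raw curves; bounded quasi-Newton optimization is run
from 10 deterministic multistart initializations (bounds: $R_{max} \in
[0, 10\max r]$, $C_{50} \in [\min c_{>0}/10,\, 10 \max c]$, $n \in [0.5,
6]$, $R_{offset} \in [-\max r, \max r]$). Each hypothesis is scored by the
variance of the attended-minus-unattended difference it accounts for,
computed about zero (one minus mean squared residual difference over mean
squared observed difference). The zero-referenced form matters: the
difference curve has a meaningful zero, and a pure vertical shift must be
fully creditable to the additive-offset model — a mean-centered variance
would score that model zero on any data. The winning label is the argmax;
ties within $10^{-9}$ resolve by the fixed precedence additive-offset >
contrast-gain > response-gain. Variance accounted for is reported
unclamped (it can be negative).

The default contrast ladder is 0 plus 12 log-spaced contrasts from 0.5% to
100%.

```{r classify, eval = FALSE}
cfg <- nma_config()
pair <- contrast_response(cfg, stimulus_spec(),
                          attention_spec("spatial", ratio = 1.4),
                          scope = "single_neuron", x = 0, theta = 0)
classify_attention_effect(pair)
```

`run_sweep()` repeats this over a grid of attention-field ratios (default
7 log-spaced values from 0.1 to 10) and modifiable baselines (default 0 to
$10^{-3}$ percent contrast; the levels spanned by the published parameter
maps are not printed anywhere, so a log-ish ladder around the stated
default was chosen). Cells where attention leaves the response exactly
unchanged are labeled `no-effect`. With the defaults, the well-tuned
neuron's baseline-0 row moves from response-gain at ratio 0.1 to
contrast-gain at ratio 10 with a single transition (near ratio 0.3);
restricting attention to the stimulus orientation shifts the transition
upward because the pool is modulated less.

### A structural note on the no-attention reference

With a single centered grating and the unattended condition defined as
"attention absent", the suppressive pool of the well-tuned neuron is
boosted almost as strongly as its numerator whenever the attention field
covers the stimulus (at ratio 1.4 the drive-weighted pool gain is about
$1 + 0.86\,(g_{peak}-1)$ versus $g_{peak}$ in the numerator). The attended
curve is then nearly an exact leftward $C_{50}$ shift, and the classifier
reports contrast-gain for any $\sigma$ — response-gain appears only for
attention fields substantially narrower than the stimulus-drive.
Experimental cued/uncued contrasts instead compare attention *here* with
attention *elsewhere*, leaving the pool similarly modulated in both states
and preserving multiplicative (response-gain) effects at ratios near 1.
Because attend-away states and multiple attention foci are outside this
package's scope, its single-stimulus no-attention comparisons place the
response-gain regime at smaller ratios than cued/uncued designs would.

## The measurement pipeline

The cortical side mirrors the published analysis chain:

1. **Localizer coherence** (`compute_coherence()`): Fourier amplitude at
   the stimulus frequency over the root sum of squared amplitudes at all
   nonzero frequencies up to Nyquist. The denominator deliberately sums
   over *all* frequencies — a single-frequency denominator would make
   coherence identically 1.
2. **Event-related amplitudes** (`estimate_amplitudes()`): a
   finite-impulse-response design (one regressor per condition and lag)
   solved by least squares under linear superposition of overlapping
   responses, then a gamma fit to each deconvolved response. The gamma
   shape is $h(t) \propto ((t-\delta)/\tau)^{k-1} e^{-(t-\delta)/\tau}$
   with $k$ fixed at 6 and amplitude parameterized as the fitted peak;
   "single-gamma" admits many parameterizations and this one keeps the
   peak — the quantity used as the response amplitude — an explicit
   parameter. `fit_r2` of the gamma fit gauges response reliability.
3. **Voxel attributes** (`voxel_sensitivities()`): contrast-sensitivity is
   the OLS slope of the cue-averaged amplitude against pedestal contrast
   (12.5/25/50%) on a linear axis, computed only for voxels with
   `fit_r2 > 0.7` (others are excluded and counted); cue-sensitivity is
   mean cued minus mean uncued amplitude regardless of contrast.
4. **Spatial profiles** (`bin_profile()`): 17 one-degree eccentricity bins
   spanning $[-8.5, 8.5]$° around the grating center (the bin count is
   fixed by the published analysis; the edges are not, and a 1° width
   centered on the grating is the natural choice). Per-subject binning
   with equal-weight subject averaging precedes fitting. The grating
   center itself comes from `locate_grating_center()`: the mean
   eccentricity of voxels with localizer coherence above 0.5.
5. **Gaussian fits** (`fit_spatial_gaussian()`): sensitivity profiles use
   a single Gaussian with mean and offset fixed at zero; the amplitude
   profile uses a sum of two Gaussians (foveal component mean constrained
   below $-2$°, stimulus component mean fixed at 0) plus one common
   offset — per-component offsets are not separately identifiable in a
   sum, so a single offset parameter is fit. Amplitudes and offsets enter
   linearly and are profiled out; the nonlinear parameters are optimized
   from deterministic multistarts (a coarse log-spaced scan brackets the
   single-Gaussian width before refinement).
6. **Bootstrap** (`bootstrap_sigma_difference()`): voxels are resampled
   with replacement within each subject (subjects fixed; the resampling
   unit is not stated in the published procedure and voxels-within-subject
   is the assumption here), profiles rebuilt, Gaussians refit, and the
   width difference wide-minus-narrow recorded, with "wide" designated by
   the caller's hypothesis (cue wider than contrast). The one-tailed p is
   the fraction of non-positive differences; with none in 10,000
   iterations the bound $p < 10^{-4}$ is reported (`p_is_bound = TRUE`).
   The two datasets are resampled independently, iterations failing to fit
   are tolerated up to 5%, and the whole procedure is bit-reproducible
   from its seed without disturbing the caller's RNG stream.

## Synthetic data

`generate_voxels()` draws eccentricities uniformly over $[-8.5, 8.5]$° and
constructs condition amplitudes so that the pipeline's estimators recover
the generating structure exactly in the noiseless limit: the cue-averaged
amplitude is linear in contrast with slope following a Gaussian profile of
SD `sigma_contrast = 3.44`°, the cued-uncued difference follows a Gaussian
of SD `sigma_cue = 4.92`°, and the overall amplitude is a sum of a foveal
Gaussian (mean $-6$°, SD 2.03°) and a stimulus Gaussian (SD 2.17°).
Independent Gaussian noise (SD 0.1% signal change per condition amplitude,
a magnitude that leaves single-subject bins visibly noisy but group
profiles stable) is added per amplitude entry; only dispersion bars are
published for the real data, so independent Gaussian noise is the assumed
law. Defaults are 5 subjects of 2000 voxels. An optional negative annular
surround (`surround_amp`, off by default) emulates responses turning
negative beyond the stimulus band. Localizer coherence is high inside a
±3° stimulus band and low outside. Every dataset carries a ground-truth
attribute (and JSON sidecar via `write_voxels()`) with the generating
parameters and per-voxel expectations.

What the generator does *not* emulate: spatial correlation between voxels,
hemodynamic nonlinearity, subject-level width variability, and non-Gaussian
noise. Recovery results on synthetic data therefore demonstrate estimator
correctness, not robustness to those realities.

With 1° binning, the fitted SD of a 3.44° Gaussian is biased upward by
roughly 0.3% (bin means average the curve over the bin); the bias applies
to both sensitivity profiles and essentially cancels in their ratio.

## Problem sizes and determinism

The test suite exercises: classifier recovery on 600 noisy pairs (noise SD
2% of $R_{max}$; ≥90% recovered), width-ratio recovery on 100 replicate
synthetic experiments at the default 5×2000 voxels (≥95% within 10% of the
generating 1.4), type-I calibration of the bootstrap on 100
equal-width replicates at 1000 iterations (p ≤ 0.05 in at most 10%), and a
full 10,000-iteration bootstrap on separated widths reporting the
$10^{-4}$ bound. All stochastic components are seeded; model evaluation,
fits and sweeps are deterministic.

## Limitations

* 1-D space: a single radial axis, one attention focus, no attend-away
  condition; consequences for the location of the response-gain to
  contrast-gain transition are discussed above.
* No temporal dynamics in the neural model; the measurement side assumes
  exact linear superposition of event-related responses.
* The three-hypothesis classification deliberately frees one parameter at
  a time; mixed effects (e.g. simultaneous $R_{max}$ and $C_{50}$ change)
  are reported only through which single-parameter model fits best and by
  how much (`margin`).
* $\sigma$ and the attention peak gain are conventions, not measurements;
  conclusions that depend on the absolute position of the classification
  transition should sweep them.

## References

* Reynolds, J.H. & Heeger, D.J. (2009). The normalization model of
  attention. *Neuron*, 61(2), 168-185.
* Naka, K.I. & Rushton, W.A.H. (1966). S-potentials from colour units in
  the retina of fish. *Journal of Physiology*, 185, 536-555.
* Heeger, D.J. (1992). Normalization of cell responses in cat striate
  cortex. *Visual Neuroscience*, 9, 181-197.
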