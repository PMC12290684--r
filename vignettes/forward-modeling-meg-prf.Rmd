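---
title: "Forward modeling of MEG event-related fields from fMRI population receptive fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modeling of MEG event-related fields from fMRI population receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfmeg)
```

## The model

A population receptive field (pRF) summarizes the region of visual space that
drives the aggregate response of the neural population at one cortical-surface
vertex. Here a pRF is a unit-amplitude 2D Gaussian in visual space,

$$g_v(x, y) = \exp\!\left(-\tfrac{(x - x_0)^2 + (y - y_0)^2}{2\sigma^2}\right),$$

with center $(x_0, y_0)$ and spread $\sigma$ in degrees of visual angle.
`prfmeg` asks a simple question of such a map: if the pRFs estimated from slow
fMRI measurements are correct, how well do they explain fast,
millisecond-resolved MEG responses to localized stimuli — and when?

The forward chain is entirely linear:

1. **Cortical prediction.** For each vertex $v$ and each binarized stimulus
   aperture $m_s$ on a visual-field pixel grid, the predicted cortical
   response is the overlap $C_{vs} = \sum_{\text{pixels}} g_v \cdot m_s$
   (`predict_cortical()`).
2. **Sensor projection.** A gain (lead-field) matrix $G$ (sensors × vertices)
   maps cortical activity to sensors: $P = G\,C$ (`project_to_sensors()`).
   The gain matrix is consumed as an input; computing it from anatomy is out
   of scope.
3. **Time-resolved cross-validated fit.** The measured epochs (−100 to 600 ms
   around stimulus onset, 1 kHz) are baseline-corrected by subtracting each
   epoch's mean over −100–0 ms per sensor. For each of 120 split-half folds,
   the epochs of each stimulus are randomly halved into train and test sets
   and averaged into event-related fields (ERFs). At each fold, sensor and
   latency, a single scaling factor fitted on the training ERF,
   $b_1 = \sum_s p_s y_s / \sum_s p_s^2$ (offset fixed at 0, because the data
   are baseline corrected), brings the 18-stimulus prediction vector to ERF
   units, and the scaled prediction is scored on the test ERF with
   cross-validated variance explained,
   $\mathrm{VE} = 1 - \mathrm{RSS} / \mathrm{TSS}$, where TSS is the
   **uncentered** sum of squared test values over stimuli. VE is bounded
   above by 1, unbounded below, and equals 0 for a zero scaled prediction.
4. **Summaries.** Per sensor and latency the package reports the median VE
   over folds with a 95% percentile interval. Sensor averages pool
   $1 - \sum_s \mathrm{RSS}_s / \sum_s \mathrm{TSS}_s$ (never the mean of
   per-sensor VEs, which would overweight low-signal sensors). Sensor groups:
   *active* (median VE ≥ 50% anywhere in the window), *early* (≥ 50% within
   50–150 ms), *earliest* (the 25% of sensors crossing 50% first after
   onset; with 306 sensors, 76).
5. **Perturbation.** `run_shift_analysis()` rotates all pRF centers about
   fixation by −90…90° and refits with the *same* folds, so differences
   between angles are attributable to the rotation, not resampling. If the
   ERFs are driven by the estimated retinotopy, VE should fall with
   increasing rotation; latencies where a rotated fit's CI falls entirely
   below the unrotated CI are flagged.

## Stimuli

Two generators cover both acquisitions. The pRF-mapping sequence
(`fmri_bar_sequence()`) sweeps a 1.25°-wide bar across a 10.68° circular
window in 20 discrete 1.5 s steps, in 8 configurations (4 orientations × 2
opposing directions), with a 15 s mean-luminance blank after every two
passes. The MEG set (`meg_stimulus_set()`) is fixed at 18 apertures on a
9.77° window: 10 bars (horizontal/vertical at offsets 0, ±1.28°, ±3.06°) and
8 circles (each quadrant at eccentricity 1.28° with diameter 1.25°, and at
3.06° with diameter 2.5°). Predictions use binarized apertures; the
checkerboard texture inside them is irrelevant to the overlap model and is
not rendered.

Conventions fixed here, where the underlying design is silent:

* **Circle placement.** The circles are centered on the 45° diagonal of their
  quadrant — the symmetric choice; only "one of the four quadrants" is
  specified by the design.
* **Coordinates.** Cartesian degrees, fixation at the origin, +x right, +y
  up; polar angle counterclockwise from +x. Display-style conventions
  (upper vertical meridian → horizontal → lower vertical meridian) are a
  relabeling of this internal convention. Positive `shift_polar_angle()`
  rotations are counterclockwise.
* **Pixel membership.** A pixel belongs to a shape iff its center does
  (deterministic half-open rule). Mask areas converge to the analytic shape
  areas as the grid is refined; the default grid is 101 × 101 pixels, which
  keeps masks within ~2% of analytic areas while the coarse-to-fine pRF fit
  is insensitive to resolution.
* **Gaussian support.** pRF Gaussians are sampled on the full grid, not
  truncated at the window; the unit-amplitude (not unit-volume) convention
  means all scale is absorbed by the fitted amplitude, but it changes raw
  overlap magnitudes — compare overlaps only under one convention.

## pRF estimation from BOLD

`predict_bold()` multiplies a candidate Gaussian with each frame of the bar
sweep and convolves the resulting time course with a two-gamma HRF
(`hrf_kernel()`, coefficients (1, 1, 0) for the canonical kernel, its
temporal derivative and dispersion derivative; canonical shape peaking near
5 s). `fit_prf()` is a two-stage coarse-to-fine search: a coarse grid of
polar-sampled positions × log-spaced sizes (amplitude fitted by least squares
at every candidate, lowest index winning ties), then Nelder–Mead refinement
of $(x_0, y_0, \log\sigma)$ seeded at the coarse winner, with positions
clipped to the search disc. The coarse-grid density and the refinement
optimizer are this package's choices; the r² reported here is the
conventional mean-referenced coefficient of determination of the BOLD fit
(the uncentered definition applies only to the ERF fit). Vertices enter the
forward model if they are not under a vein, reach r² ≥ 0.15 (inclusive), and
have centers inside the stimulated window (inclusive); excluded vertices are
zeroed, not dropped, to keep gain columns aligned.

## What the synthetic generator emulates

`synthetic_scene()` + `simulate_epochs()` produce a fully specified dataset
with known ground truth. Its defaults are the package's study conditions and
are not tuned per analysis:

| parameter | default | why |
|---|---|---|
| vertices | 500 | enough for smooth sensor profiles; minutes-scale runtime |
| sensors | 60 | resolves the visual-field topography of the gain model |
| epochs/stimulus | 60 | the regime of a realistic MEG session block |
| time axis | −100…600 ms @ 1 kHz | the analysis window and sampling of the method |
| folds | 120 | the method's cross-validation depth |
| signal peak | 100 units | reference amplitude of the best sensor's template |
| noise SD | 100 units/sample | single-epoch peak SNR ≈ 1, typical of visual ERFs |

pRF centers are uniform over the stimulated disc with the empirical
eccentricity–size coupling $\sigma = 0.3 + 0.15\,\mathrm{ecc}$; r² is drawn
in (0.15, 1] so every vertex passes selection. The synthetic gain assigns
each sensor a preferred visual-field locus (sunflower layout) with Gaussian
spatial decay (2° spread), multiplied by a smooth signed polarity field of
pRF position — so nearby vertices mix coherently while distant ones can
cancel, the property of lead fields that matters for this pipeline — plus
small jitter that makes the matrix full rank. **No dipole physics is
modeled**: the pipeline's contracts are linear-algebraic, and a
spherical-head generator could replace this one behind the same interface.
The evoked kernel is zero until 50 ms, biphasic with peaks near 100 and
200 ms and a dip near 150 ms, decayed by 300 ms — the shape of early visual
evoked fields. Noise is white Gaussian per sample (temporally correlated
noise is not simulated), epochs are balanced across the 18 stimuli, and all
randomness flows from one master seed (bit-identical reruns).

Passing tests on these scenes therefore show that the *pipeline* recovers
what it should when the forward model holds exactly and noise is white. They
do not show robustness to co-registration error, gain-model mismatch,
correlated or non-stationary noise, eye movements, or trial-to-trial
amplitude variability — all present in real recordings.

## Numerical choices and degenerate inputs

* Undefined fits propagate as `NA`, never 0: an all-zero prediction vector
  leaves $b_1$ undefined; a zero test TSS (possible only in noiseless
  simulation, where the kernel is exactly 0) leaves VE undefined. `NA` folds
  are excluded from medians and CIs; pooled averages exclude undefined
  sensors cellwise.
* The 95% CI is the 2.5th–97.5th percentile across folds with the
  linear-interpolation (type 7) definition, fixed for bit-reproducibility.
  Whether a percentile interval is the right CI is a design choice; with 120
  folds the distinction from other definitions is small.
* Sensor-group membership thresholds the fold-*median* VE; first-crossing
  latency is the first sample at or after stimulus onset with median VE ≥
  threshold, ties broken by sensor index.
* CI non-overlap for the perturbation analysis is one-sided (rotated fit
  worse) and conservative: intervals sharing an endpoint count as
  overlapping.
* Odd epoch counts put the smaller half in training. Folds are independent
  random splits; partitions can in principle repeat across folds
  (astronomically unlikely at realistic epoch counts).
* RSS is computed from sufficient statistics and clamped at 0 against
  rounding; splits, fold averages and fits are exactly reproducible from the
  fold seed, and a multi-angle run is bit-identical to fitting each angle
  alone.
* `fit_scale()` with an offset (`fit_scale_with_offset()`) is plain OLS of
  the training ERF on (prediction, constant). The offset model is reported
  alongside the default zero-offset model; on data whose across-stimulus mean
  is shifted at late latencies, the offset variant explains more there and
  matches the default model during the early evoked response.
* Rotated pRFs keep their inclusion mask frozen at the unshifted state, even
  if a rotated center leaves the window — re-filtering would change the
  vertex set between angles and break the paired comparison.

## Problem sizes

The default scene (500 vertices, 60 sensors, 1080 epochs, 120 folds, 701
latencies) fits in about 15 s on one core; a full 9-angle perturbation run
completes in under a minute thanks to shared fold averages. The package's
tests exercise the complete pipeline at these default conditions, and use
smaller scenes (tens of vertices and sensors, a handful of folds) for
unit-level checks where the full scale adds nothing.

## Known limitations

* The gain matrix is an input (or synthetic); there is no anatomy-based
  forward solution, orientation constraint, or head-movement compensation.
* Magnetometers and gradiometers are treated as independent sensors with
  independent fits; no unit harmonization or scalp-topography statistics.
* Eccentricity and size perturbations are deliberately absent; only polar
  angle is perturbed.
* The BOLD side simulates percent-signal-change time courses directly; raw
  fMRI preprocessing, surface extrapolation and vein masking are upstream of
  this package.
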