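---
title: "Quantifying crowding-stress skin colour change in Atlantic mackerel"
author: "bluemack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying crowding-stress skin colour change in Atlantic mackerel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bluemack)
```

## The problem

Atlantic mackerel (*Scomber scombrus*) are highly sensitive to the
crowding that occurs when a purse seine is tightened around a school.
Under crowding stress the light inter-stripe regions of the dorsal
skin shift from green towards blue; in CIELAB terms, the b*
(blue–yellow) coordinate falls. If that shift can be quantified from
photographs it becomes a practical, real-time welfare indicator:
blueness can be read off a camera while a catch is still in the net,
whereas plasma chemistry cannot.

`bluemack` implements the complete quantification chain and, because
no field data are distributed with it, a synthetic-data module that
generates every input with known ground truth: rendered dorsal images
through a distorting camera, b* trajectories under crowding, a
physiology cohort, post-mortem series and mortality counts. The
statistical layer — GLS with group-wise variance weights,
random-intercept mixed models, penalized-spline mixed models, Wald-F
and likelihood-ratio tests, Wilson intervals — is written from
scratch in the package, with `nlme` and `mgcv` used purely as
independent cross-checks in the test suite.

## Imaging and calibration model

A photograph enters the pipeline as an 8-bit sRGB image. The camera
and flash are modelled in linear RGB as

$$ c = Q\!\left(E\left(g\,h\,M\,r\right)\right), $$

where $r$ is the true linear-RGB colour, $M$ a near-identity
3×3 colour distortion, $g$ the flash gain (drawn uniformly in
[0.7, 1.3] per image, emulating flash-to-flash inconsistency), $h$ a
fixed highlight-protection headroom, $E$ the sRGB transfer and $Q$
8-bit quantization.

The headroom factor (default 0.75 in the random camera) reflects raw
capture practice: a photographer fixing manual settings leaves
highlight headroom so that a bright white background never clips even
at the top of the flash-gain range. Without it, gains above about
1.14 would saturate the white background, destroying the exposure
anchor; with it, the perturbation stays invertible, and since the
headroom enters exactly like the gain it cancels through exposure
normalisation without any special handling.

Calibration proceeds in the order **decode → exposure-normalise →
matrix-correct → convert**:

1. **Decode.** The standard sRGB piecewise transfer maps encoded
   values to linear light.
2. **Exposure normalisation.** Each image carries a white reference —
   the background the fish lies on (ground truth L* = 95), or the
   brightest neutral patch of the chart. "Intensity" is the mean
   linear green value over the reference region (green approximates
   luminance); the image is rescaled so this mean hits the known
   reference value. A region mean at or above 0.99 before scaling is
   flagged as saturated and the gain marked unreliable.
3. **Matrix correction.** A synthetic 24-patch chart (six-step grey
   ramp, saturated and dark chromatic patches, natural mid-tones — a
   deterministic lattice spanning the gamut, standing in for a
   commercial colour checker) is imaged through the same camera
   matrix. The unconstrained least-squares 3×3 matrix mapping
   measured to reference patch values undoes $M$; with exposure
   handled in step 2 no offset term is needed for flash-lit,
   black-level-subtracted capture.
4. **Conversion.** Linear RGB → XYZ (published sRGB/D65 primaries) →
   CIELAB against the D65 white point. D65 is used throughout; it is
   the native white of the sRGB encoding the images arrive in.

Because the exposure anchors of the chart (neutral grey) and the fish
image (near-neutral white background, b* = 2) are not exactly
proportional, the composed correction is exact only to first order in
the distortion; for near-identity matrices the residual error is well
below the ΔE*ab < 1 recovery tolerance, which the test suite verifies
end to end across random cameras.

## ROI measurement

The measured region is the standard 530 × 53 pixel strip along the
right dorsal axis, supplied per image in the metadata (ROI placement
is a manual step in field practice). Dark stripes are excluded by
thresholding the *green* plane of the thumbnail — dark stripes are
dark in every channel, light skin is brightest in green — using
Otsu's method, which is automatic and parameter-free; a fixed
threshold can be forced through configuration, and the threshold
actually used is recorded with every measurement for audit. Each kept
pixel is decoded, gain-scaled, matrix-corrected and converted
individually, and L*, a*, b* are averaged **after** conversion:
averaging RGB first and converting once would be wrong under the
nonlinear transforms.

Fewer than 50 surviving pixels flags a measurement unreliable rather
than failing the batch.

## Crowding density

The experimental cage is a 5 × 5 × 5 m box over a pyramidal bottom
with total volume 149.17 m³. The pyramid depth is not stated
anywhere, so the package derives it from the volume identity
$149.17 = 5^2\cdot 5 + \tfrac13\,5^2\,d$, giving $d = 2.9004$ m.
A crowded school concentrated in the bottom section is treated as a
geometrically similar shrinking of the full pyramid: from an observed
surface area $A$, the linear scale is $k = \sqrt{A/25}$, the depth
$k\,d$, the volume $A\,(k\,d)/3$ (identical for right cones and right
pyramids), and density is biomass over that volume. The similarity
construction is an explicit stand-in: the original trigonometric
depth derivation is not recoverable, and published per-trial
densities are treated as given inputs, never as recomputation
targets.

## Statistical models

All models are Gaussian, estimated by REML by default, and share one
engine: the marginal likelihood of
$y = X\beta + \sum_k Z_k u_k + \varepsilon$ with
$u_k \sim N(0, \sigma^2\psi_k I)$ and
$\mathrm{Var}(\varepsilon_i) = \sigma^2 v_i$, where $\beta$ and
$\sigma^2$ are profiled out in closed form and the remaining
log-variance parameters are maximised by Nelder–Mead simplex from
three fixed starting points (0, +1, −1 on the log scale),
convergence at 1e−10 relative change.

* **Group-wise variance weights** (the GLS and LME residual
  structure): $v_i = \delta_{g(i)}^2$ with the alphabetically first
  level fixed at $\delta = 1$. With one group the GLS collapses
  exactly to OLS.
* **Power-of-mean variance** (the spline models):
  $v_i = |\mu_i|^{2\delta}$ with a floor of 1e−6 on $|\mu_i|$ to
  avoid zero-mean singularities; fitted means and variance
  parameters are updated by iterative reweighting (at most 8 outer
  iterations, relative tolerance 1e−6).
* **Random intercepts**: one grouping factor or two nested factors
  (monitoring period within trial; fish for repeated post-mortem
  measures). Singular fits are reported with the SD estimated at the
  boundary, not raised as errors.
* **Penalized cubic splines**: a cubic B-spline basis with a
  second-derivative penalty, rewritten in mixed-model form via the
  penalty eigendecomposition — the straight-line null space joins
  the fixed effects, the wiggles become a random-effect block whose
  variance ratio is the inverse smoothing parameter, estimated by
  REML like any other variance component. The basis dimension is
  chosen from the candidates (5, 8, 10, 12) by ML-based AIC whose
  model size counts *effective* degrees of freedom (trace of the
  smooth's influence matrix), not raw basis size.
* **Inference**: Wald-F for GLS terms
  ($F = (L\hat\beta)^\top(L\hat V L^\top)^{-1}(L\hat\beta)/q$ against
  $F(q,\,n-p)$); likelihood-ratio tests for mixed-model terms, always
  on ML refits when fixed effects differ — REML likelihoods are never
  compared across fixed-effect structures. Screening terms (vitality;
  post-mortem storage) are dropped when non-significant at 0.05, with
  the decision recorded. Temporal autocorrelation structures are
  deliberately absent from the toolkit. Mortality proportions get
  Wilson score intervals, which stay inside [0, 1] and behave at zero
  counts (upper bound exactly $z^2/(n+z^2)$).

Treatment contrasts with the alphabetically first level as reference
are used for all categorical terms, so coefficients are deterministic
across platforms.

## What the generators emulate — and what they do not

The generator defaults are the study conditions. Where the source
analysis reports a value it is used directly: baseline b* 17.17 (the
control mean, also reused for crowded trials whose baselines are not
printed), per-minute b* rates −0.25 (Low), +0.30 (Moderate), −0.82
(High), −0.20 (High & Prolonged), trial durations and densities from
the trial table, post-mortem sampling at 0, 1, 4, 24 h with no
storage effect. Values the source does not print were fixed once at
plausible magnitudes and are config-overridable: residual SD 2.0 b*
units, trial and period intercept SDs 1.0, post-mortem blue shift 5
b* units with baseline SD 1.5 and measurement SD 1.0, dark-stripe
Lab (20, −2, 0), background Lab (95, 0, 2), and a monotone-decreasing
logistic lactate→b* link falling from 20 to 5 b* units around 8
mmol/L (plasma glucose and cortisol are simulated with no b* signal,
matching their lack of predictive value).

Trajectories are linear drifts with Gaussian noise sampled uniformly
over the exposure window; real trajectories need not be linear, and
real residuals need not be Gaussian or independent. The renderer
draws crisp axis-aligned stripes with spatially constant colour — no
scales, fins, curvature, specular residue or texture. Passing tests
therefore demonstrate that the pipeline recovers known colours and
effect sizes through a realistic camera/exposure distortion, not that
it is robust to fish-shaped geometry or field lighting. One
consequence of the untextured rendering is visible in the recovery
numbers: a spatially uniform colour quantizes to the same 8-bit code
in every pixel, so rounding error does not average out across pixels
and contributes a deterministic offset of up to a few tenths of a ΔE
unit — well inside the ΔE*ab < 1 recovery criterion, but not
reducible by averaging.

The moribund-fish blueness band is only ever shown graphically in the
source and is not simulated as a distinct class; trial-specific
baselines are likewise a configuration choice, not data-derived.

## Numerical choices and degenerate inputs

Encoded values are clipped to [0, 1] before transfer functions;
out-of-gamut scene colours abort rendering. A constant thumbnail
cannot be thresholded and is kept whole with a warning. Rank-deficient
chart patch sets (fewer than three non-coplanar patches) abort the
correction fit. Optimizer non-convergence is reported on the fit
object, not raised. The brute-force REML grid oracle in the tests
uses a fine local grid (±10% around the estimates) because a coarse
grid's discretisation error would exceed the 1e−3 agreement bound
being verified.

Problem sizes in the tests and acceptance script — 40 fish per
scenario per replicate, 10 replicates per scenario, 500-replicate
null calibrations, 300-observation spline fits — were chosen so each
check has clear statistical margins while the whole suite stays
comfortably fast on a single CPU.

## Known limitations

* The colour pipeline assumes a linear camera after sRGB decoding; no
  ICC profiles, raw demosaicing or chromatic adaptation between
  illuminants.
* The exposure anchor must be near-neutral; strongly tinted
  backgrounds would push the first-order normalisation error up.
* No autocorrelation structures, crossed random effects or
  non-Gaussian responses in the statistics layer.
* The field data behind the original analysis are not available, so
  the package's recovery experiments validate the *method* against
  its own generators, not against the original photographs.
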