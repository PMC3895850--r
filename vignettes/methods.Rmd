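---
title: "Measuring circumferential aortic wall stretch from displacement-encoded MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring circumferential aortic wall stretch from displacement-encoded MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortastretch)
```

## The measurement model

Displacement encoding with stimulated echoes (DENSE) stores the motion
of tissue between a position-encoding pre-pulse and the readout in the
phase of the MR signal. For an acquisition with encoding frequency
$k_e$ (cycles/mm) and net encoding direction $\mathbf d$ (after
subtracting a reference acquisition), a voxel whose tissue moved by
$\mathbf u$ (mm) carries the wrapped phase

$$\varphi = 2\pi k_e\, (\mathbf d \cdot \mathbf u) \pmod{2\pi}.$$

Here the pre-pulse is applied at maximal aortic expansion and the
readout in diastole, so $\mathbf u$ carries tissue from the *expanded*
state to the *resting* state. Two consequences shape the pipeline:

* The expanded position of a resting point $\mathbf x$ is recovered by
  *subtraction*, $\mathbf x_{sys} = \mathbf x - \mathbf u(\mathbf x)$.
  The sign convention is stated explicitly throughout because nothing
  in the phase data itself disambiguates it.
* Blood that was encoded leaves the slice before readout, so the lumen
  contributes almost no signal (the black-blood effect). Magnitude is
  therefore a usable per-pixel reliability measure for the phase.

With at least three independent net directions the per-pixel
displacement is the least-squares solution of
$2\pi k_e D \mathbf u = \boldsymbol\varphi_{net}$, where $D$ stacks
the net direction rows. `decode_displacement()` accepts arbitrary
direction sets and rejects rank-deficient ones; the phantom uses a
reference acquisition plus the three unit net directions of a
symmetric tetrahedral (balanced 4-point) scheme.

## Stages and the parameters that matter

### Wall delineation

The inner, outer and mid wall are closed periodic cubic splines
through operator control points (`fit_closed_curve()`), reparameterized
by arc length so that equal parameter steps are equal arc steps to
well below 0.1%. Wall pixels are those whose centres lie between the
inner and outer contours; of these, pixels with magnitude below
`exclusion_fraction` (default **0.3**, dimensionless) times the median
candidate magnitude are excluded. No threshold is inherent to the
method; 0.3 removes black-blood and partial-volume pixels in the
phantom without eroding the one-to-two-pixel-wide wall, and it is
exposed in the configuration. When no explicit mid-wall contour is
supplied, the mid curve is the mean-radius curve of inner and outer
along rays from their common centroid (valid for star-shaped vessel
sections, which cross-sections of the ascending aorta are).

### Phase smoothing: normalized averaging

Wrapped phase cannot be smoothed directly; the package smooths the
unit-complex representation with certainty weights,

$$\tilde\varphi = \arg\frac{G_\sigma * (c\, e^{i\varphi})}{G_\sigma * c},$$

with certainty $c = \text{magnitude}^p$ zeroed outside the wall mask
(exponent $p$ default **1**; the reliability of DENSE phase is
monotone in magnitude, and the linear choice is the simplest member of
the family, with $p$ configurable) and a Gaussian applicability of
**sigma = 1 pixel** (the method's standard smoothing scale for this
application; larger values visibly bias the thin wall's displacement
field, see the noise discussion below). Output pixels whose smoothed
certainty falls below $10^{-3}$ times its maximum have no support and
are flagged invalid rather than returned as amplified noise. Because
the certainty is zero outside the wall, the smoothed phase extends a
few pixels beyond the wall with values borrowed from wall pixels —
deliberately, since sub-pixel interpolation at the mid-wall needs a
valid neighbourhood.

### Unwrapping: weighted least squares with a DCT-preconditioned solver

`unwrap_poisson()` minimizes the weighted squared deviation between
the gradients of the unwrapped field and the wrapped gradients of the
input, with zero weight on gradients that cross pixels outside the
mask. The normal equations are a weighted Poisson problem with
Neumann boundaries on the full rectangle. A single cosine-transform
(DCT) solve inverts the *unweighted* problem exactly; with a masked
domain a single solve leaks across the mask boundary, which matters
here because the wall is thin — every wall pixel is a boundary pixel.
The package therefore runs conjugate gradients on the weighted normal
equations with the DCT solve as preconditioner (relative residual
tolerance $10^{-12}$, cap 500 iterations; uniform weights converge in
one application). For residue-free inputs — any field whose masked
neighbour differences are consistent — the true field is recovered on
the mask to machine precision, up to a constant.

The additive constant is fixed so that the certainty-weighted median
of (unwrapped − wrapped) over the mask is the nearest multiple of
$2\pi$: the unwrapped field then agrees with the measured phase
modulo $2\pi$ at the median pixel, and a spatially constant true
phase passes through unchanged (wrapped branch and all), which keeps
the decode unbiased when fewer than half of the wall pixels wrap.

The pipeline unwraps each reference-subtracted ("net") phase image
separately, on the support region where normalized averaging produced
valid output (the Gaussian-dilated wall), not on the bare wall mask —
unwrapping on the bare mask would fill the near-wall ring with
harmonic values inconsistent with the smoothed phase and corrupt
sub-pixel interpolation. Whether per-net-image unwrapping or
post-decode unwrapping is preferable is not determined by the method
description; per-net-image is implemented because it keeps the
unwrap input closest to the measured data.

### Tracking and the stretch profile

`seed_points()` places **n = 100** points (configurable, minimum 8) at
equal arc spacing on the diastolic mid curve, starting at the anterior
axis crossing and advancing anterior-to-right. Displacement components
are sampled at sub-pixel locations with Keys bicubic interpolation;
footprint pixels with zero certainty or invalid decode are excluded
and the remaining weights renormalized, so interpolation degrades
gracefully at the support edge instead of failing or zero-filling.

Both the diastolic points and the tracked systolic points are then
regularized with a periodic uniform cubic B-spline with **5 pieces**
fitted by least squares against the point index, and each point is
projected to the nearest parameter on its spline. The per-segment
stretch is the ratio of distances between adjacent projected points,
systolic in 3-D (through-plane motion included), diastolic in-plane.

Treating *both* states with the identical spline family is a
deliberate design choice and the one place this implementation departs
from the more obvious reading (systolic spline only). A 5-piece
periodic cubic cannot represent a circle exactly: the least-squares
fit of a circle carries about 0.5% radial ripple (while preserving
perimeter to < 0.01%). If only the systolic points were spline
smoothed, that ripple would appear directly in the per-segment
stretch of an identity or rigid-motion acquisition at the 0.005
level. Because least-squares spline fitting and nearest-point
projection commute with rigid maps and with uniform scaling, applying
the same treatment to both states cancels the ripple *exactly* in the
ratio: identity gives $\lambda_i \equiv 1$ to machine precision, a
rigid motion likewise, and a uniform scaling gives exactly the scale
factor. For non-uniform deformations the residual spline bias is the
difference of two nearby approximations and stays well below the
noise floor (quadrant means recover analytic truth to ~0.03% on the
noise-free asymmetric phantom).

Chord distances between projected points are the default; arc lengths
along the splines are available (`mode = "arc"`) since the method
description admits both readings. For 100 points the two differ by
$O((2\pi/100)^2)$ in ratio and are indistinguishable at the reported
precision.

The segment's quadrant is the quadrant of its diastolic midpoint.
Quadrants are 90° sectors centred on the anatomical axes in the supine
axial convention (image $-y$ = anterior, image $-x$ = patient right;
both configurable via `slice_orientation()`); a point exactly on a
45° diagonal is assigned to the next sector in the direction of
increasing angle, a deterministic tie-break. The summary statistic per
quadrant is the relative stretch difference
$(S_{quadrant} - S_{overall})/S_{overall}$, which sums to zero over
the four quadrants whenever they contain equal segment counts.

### Cohort statistics

The unit of observation for the two-way ANOVA is the per-subject,
per-quadrant mean stretch — four rows per subject — with fixed factors
group and quadrant and their interaction, fitted with `stats::aov()`
and followed by Tukey honest-significant-difference contrasts within
each factor. How repeated quadrant measurements per subject should
enter the model is genuinely open (a mixed model with a subject effect
is defensible); the fixed-factor interpretation is implemented because
it is the simplest model consistent with reporting group and quadrant
main effects plus their interaction. Exactly zero effect sums of
squares are reported as $F = 0$, $p = 1$ rather than the indeterminate
0/0. Pearson correlation and the cine area change
$(A_{max}-A_{min})/A_{min}$ are thin validated wrappers over base R
and the shoelace formula.

## The phantom: what it emulates and what it does not

`make_phantom()` renders a resting annulus (defaults: mid radius
15 mm, wall thickness 2.5 mm, 64 × 64 grid at 2.3 mm pixels, encoding
frequency 0.08 cycles/mm, slice thickness 8 mm — the geometry regime
this pipeline targets, where the wall is one to two pixels thick) and
deforms it by scaling the mid-wall radius with
$s(\theta) = s_0 + \sum_k a_k \cos(k\theta + \phi_k)$ while preserving
wall thickness, composed with rigid in-plane rotation, rigid in-plane
translation and a constant through-plane shift. This family has a
closed-form stretch profile (evaluated by `analytic_stretch_profile()`
via step-halving numerical differentiation, converged to $10^{-8}$)
while exhibiting the expansion-plus-rotation phenomenology the method
must be invariant to.

Fidelity choices:

* **Partial volume** — pixel magnitude is the exact area fraction of
  the annulus covering the pixel (closed-form circle–polygon
  intersection), so the low-magnitude exclusion rule is exercised by
  genuinely intermediate pixels, not a binary mask.
* **Noise** — complex Gaussian noise is added to the real and
  imaginary channels of every acquisition before magnitude and phase
  extraction, reproducing the magnitude-dependent phase noise that
  motivates certainty weighting. SNR is wall magnitude over the
  per-channel noise standard deviation.
* **Black blood** — lumen magnitude defaults to 0.05 of wall
  magnitude, below the exclusion threshold; a small nonzero background
  (0.02) stands in for the noise floor outside the vessel.
* **Reference phase** — zero in the phantom; the decoder does not
  assume this and always subtracts the designated reference
  acquisition.

What the phantom does *not* emulate: the spiral k-space readout and
its artifacts, phase-cycling residuals (inputs are taken to be
post-cycling phases), respiratory or navigator motion, T1 decay of the
stimulated echo over the encoding interval (the wall magnitude is
static — the signal model is not described by the method and is
deliberately not guessed), and through-plane deformation gradients
(the shift is constant across the slice). Passing the phantom tests
therefore demonstrates the correctness and noise behaviour of the
*post-processing*, not the robustness of the acquisition to those
physical effects.

The cine lumen series scales the lumen contour homothetically with
$s(\theta)$, so a uniform scaling $s_0$ changes lumen area by exactly
$s_0^2 - 1$. This differs from the thickness-preserving wall map
(under which the lumen radius would change by $s_0 R - h/2$, not
$s_0 r_{in}$): the cine model represents the lumen-area measurement
convention, the wall map the tissue kinematics, and the package keeps
them as separate models rather than forcing one to fit the other.

## Numerical choices and degenerate inputs

* Arc-length reparameterization integrates curve speed on a 4096-point
  grid (trapezoid) and inverts with a monotone Hyman spline; residual
  speed non-uniformity is far below the 0.1% contract.
* Simplicity of delineation curves is checked by exact segment
  intersection on a 512-point polygonization; self-intersecting
  contours are a geometry error, not a warning.
* The DCT pair is implemented via FFT reordering (verified against the
  direct transform); the unwrap solver's preconditioned CG stops at a
  $10^{-12}$ relative residual.
* Projection onto the regularizing spline searches a ±0.1-period
  window around each point's index parameter, keeping projections in
  order around the circumference.
* Degenerate inputs fail loudly with classed conditions: empty wall
  mask, all-zero certainty, empty unwrap mask, zero-length diastolic
  segments, empty quadrants, rank-deficient encoding sets, missing
  seeds for stochastic stages, ANOVA tables with empty cells.

## Problem sizes used in validation

The shipped tests and the acceptance script run the full chain on
64 × 64 phantoms with 100 tracked points: single noise-free phantoms
for the identity/uniform/rigid/asymmetry recovery checks, 20 seeded
repetitions at SNR 15 for quadrant-rank stability, 50 random
band-limited fields for the unwrapping oracle, 20 fields for the
normalized-averaging oracle, a 12-phantom cohort for the
stretch–area correlation, and 100–200 seeded repetitions for the
ANOVA detection rate. These sizes make the whole suite run in about a
minute while leaving every tolerance comfortably non-trivial.

## Known limitations

* Single time-pair analysis only: one encoded displacement between two
  cardiac phases, as acquired; no multi-phase cine DENSE tracking and
  no strain tensor (radial or shear components).
* The mid-wall derivation from inner/outer contours assumes a
  star-shaped section about the centroid.
* The quadrant convention assumes an axial slice orientation; oblique
  slices must supply their own anterior/right axes.
* Stretch accuracy degrades if the wall mask loses whole quadrants to
  the magnitude exclusion (the pipeline then reports an analysis error
  rather than extrapolating).
* The ANOVA treats subject-quadrant cells as independent observations;
  with few subjects per group a mixed-effects formulation would be
  more conservative.
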