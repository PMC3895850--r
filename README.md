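# aortastretch

Quadrant-resolved circumferential wall stretch of the ascending aorta
from displacement-encoded (DENSE) MRI.

## The problem

Aortic stiffness is conventionally measured as an integrated quantity
(distensibility: relative lumen area change per unit pulse pressure),
which cannot resolve *where* around the circumference the wall is stiff.
DENSE MRI stores tissue displacement between a position-encoding
pre-pulse (applied at maximal aortic expansion) and the readout (in
diastole) in the *phase* of the MR signal: at a pixel with displacement
**u**, an acquisition with encoding frequency `k_e` (cycles/mm) and net
encoding direction **d** records the wrapped phase

```
phi = 2*pi * k_e * (d . u)      (mod 2*pi)
```

so displacement is measured per-voxel without resolving tag lines,
which is what makes the 2–3 mm thick aortic wall tractable at
2.3 mm pixels. This package implements the post-processing that turns
those phase images into a quadrant-resolved stretch profile:

1. **Delineation** — closed periodic splines through operator control
   points for the inner, outer and mid wall; wall pixels with low
   magnitude (unreliable phase) are excluded.
2. **Phase processing** — certainty-weighted normalized averaging of
   the wrapped phase (certainty = signal magnitude, Gaussian
   applicability sigma = 1 pixel), least-squares Poisson phase
   unwrapping (DCT-preconditioned conjugate gradients), then per-pixel
   least-squares decoding of 3-D displacement from the balanced
   multi-point encoding set.
3. **Tracking** — 100 points seeded equidistantly on the diastolic
   mid-wall are carried to their systolic positions through the
   displacement field (certainty-weighted bicubic sampling).
4. **Stretch** — both point sets are regularized with a 5-piece
   periodic least-squares spline; the per-segment stretch is
   `lambda_i = |P_sys,i+1 - P_sys,i|_3D / |P_dia,i+1 - P_dia,i|_2D`,
   systolic distances in 3-D (through-plane motion counts), diastolic
   distances in the imaging plane.
5. **Quadrant analysis** — segments are binned into anterior (A),
   right (R), posterior (P) and left (L) 90-degree sectors; the
   asymmetry statistic per quadrant is the relative stretch difference
   `(S_quadrant - S_overall) / S_overall`.

Cohort-level tools cover the companion measurements: cine lumen-area
change `(A_max - A_min)/A_min`, Pearson correlation of stretch against
area change, and two-way ANOVA (group x quadrant) with Tukey contrasts
on per-subject quadrant stretch.

Because no patient data are available, the package ships a synthetic
phantom: an annular wall with analytically known deformation
(circumferential stretch pattern `s(theta) = s0 + sum_k a_k cos(k
theta + phi_k)`, rigid rotation/translation, through-plane shift),
exact partial-volume rendering, black-blood lumen contrast and complex
Gaussian noise. Every stage is validated against this ground truth.

## Worked example

An asymmetric phantom whose stretch peaks on the anterior wall
(`s(theta) = 1.05 + 0.03 cos(theta - theta_A)`), imaged at SNR 20:

```r
library(aortastretch)

spec <- phantom_spec(s0 = 1.05, a = 0.03, phi = pi/2, snr = 20, seed = 1)
res  <- phantom_stretch(spec)
res$summary
#> <quadrant_summary> overall stretch 1.0506 (105.1%)
#>   A: stretch 1.0784, relative difference +0.0264
#>   R: stretch 1.0530, relative difference +0.0023
#>   P: stretch 1.0171, relative difference -0.0319
#>   L: stretch 1.0539, relative difference +0.0031

relative_area_change(make_cine_series(spec, 20))
#> [1] 0.1030
```

The overall stretch of 1.0506 recovers the imposed mean of 1.05; the
anterior quadrant is correctly identified as the most compliant
(true quadrant means are 1.077 A / 1.051 R / 1.023 P / 1.050 L), and
the relative stretch differences sum to zero by construction. The cine
lumen area change of 10.3% is consistent with a ~5% circumferential
stretch (area scales with stretch squared).

The same chain is scriptable from a shell via
`inst/cli/aortastretch.R` (subcommands `simulate`, `process`,
`stretch`, `report`, `run`, `validate`) and reproducible end-to-end
with `run_pipeline()`, which writes per-stage outputs and a checksum
manifest.

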