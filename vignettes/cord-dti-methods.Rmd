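---
title: "Methods: single-slice cord DTI processing and its phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-slice cord DTI processing and its phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordDTI)
```

This vignette documents the models, parameter choices and numerical
decisions behind cordDTI, in the spirit of a methods section: what each
stage assumes, why the defaults are what they are, and what the phantom
validation does and does not demonstrate about real data.

## The signal model and tensor fit

A single axial slice is acquired at C2 with one unweighted (b0) volume
and six diffusion-weighted volumes. The encoding directions
(1,0,1), (−1,0,1), (0,1,1), (0,1,−1), (1,1,0), (−1,1,0) — scanner frame,
z parallel to the cord — are normalised to unit length. The b-value is
configurable with a default of 800 s/mm², a typical choice for
cervical-cord DTI at 3 T (the sequence's exact b-value is
protocol-dependent and not hard-coded anywhere downstream).

Per pixel the signal follows the single-tensor model
`S_v = S0 · exp(−b_v · g_vᵀ D g_v)`. Taking logs gives a linear system in
the six unique tensor elements and `ln S0`; with exactly seven volumes
the design matrix is square and full rank, so the log-linear solve is
exact for noiseless data and unweighted least squares for more volumes.
A weighted or nonlinear fit would differ only in noise propagation, not
in the estimand, and is unnecessary at the effective SNR of averaged
acquisitions (below). Negative eigenvalues are clamped to zero and
flagged per pixel rather than discarding the pixel — a single-slice cord
has too few pixels to spare. FA of the all-zero tensor is defined as 0
(the formula is 0/0). The identity MD = (AD + 2·RD)/3 holds by
construction and is asserted pixelwise in the tests.

Worth noting: for a tensor whose principal axis lies along z, the six
directions attenuate in two groups — the four directions mixing one
in-plane axis with z see `(λ⊥ + λ∥)/2`, while (1,1,0) and (−1,1,0) are
purely in-plane and see `λ⊥` alone. The scheme is rank-complete but not
isotropically balanced; the tests assert this 4 + 2 grouping explicitly.

## Motion correction

Breathing displaces the cord along the anterior–posterior (phase-encode)
axis between volumes. Correction uses midsagittal intensity profiles:
the mean over a 5-pixel-wide band of columns centred on the image
midline (fractional column weights keep the band symmetric for any grid
parity), one value per row.

The general-purpose displacement estimator, `estimate_ap_shift()`, is
normalised cross-correlation over integer lags with parabolic sub-pixel
refinement. It is accurate when target and reference share contrast —
but the b0 and the weighted volumes do not: CSF is the brightest tissue
on b0 and nearly the darkest on a weighted volume. On phantom data this
contrast inversion biases NCC against the b0 by up to 0.8 px even when
no shift was injected. `motion_correct()` therefore defaults to a
floored centre-of-mass estimator: both profiles are floored at their
median and the displacement is the difference of their centres of mass,
which coincide at the cord for either contrast. Phantom recovery errors
are ≤ 0.03 px noiseless and ≈ 0.15 px at SNR 20; injected shifts up to
±3 px are recovered within 0.25 px. NCC remains available via
`estimator = "ncc"`.

Only the anterior–posterior axis is corrected, the b0 is never
resampled, translations are spectral (circular, exact for band-limited
content; the real-valued Nyquist projection makes fractional shifts
slightly lossy at the Nyquist frequency only), and no eddy-current
correction is applied anywhere. The auto-crop margin defaults to 4 px so
that a displaced cord stays inside the intraspinal box.

## Interpolation

Metric maps — never the raw DWI — are upsampled to 0.2 × 0.2 mm² before
ROI work, by separable Catmull–Rom bicubic interpolation with linear
border extension (linear ramps pass through unchanged, including the
extrapolation strip). The output grid is centred on the source image so
that a left–right symmetric input remains exactly mirror-symmetric on
the fine grid; the grid origin is carried alongside the map and used for
ROI snapping. All four metric maps are interpolated, for consistency
(whether a study interpolates all maps or FA only is usually
unreported; interpolating all four costs nothing and keeps the ROI
machinery uniform).

No installed package offers 2-D cubic interpolation at scattered
points, so this interpolator is implemented in the package and verified
against its exactness properties in the tests.

## The ellipse / angular-profile segmentation

The semi-automated column segmentation works on the FA map:

* **Cord mask.** FA threshold (Otsu within a signal-support mask;
  absolute fallback configurable) + largest connected component. The
  support mask — pixels brighter than the b0's Otsu threshold — is
  essential on noisy data: a pure-noise background pixel has high
  apparent FA, so FA alone cannot separate cord from background, but
  background is dark on b0.
* **Initial ellipse.** First and second spatial moments of the mask (a
  filled ellipse has semi-axis = 2 SD), shrunk by 0.63 so the sampling
  path crosses the gray-matter horns and white-matter columns.
  Validation on phantoms fixed this value: at 0.60 the posterior arc
  runs through the horn-wedge partial-volume zone, at 0.65 the
  dorsal-column RD picks up CSF partial volume.
* **Profile.** FA sampled at 600 uniformly spaced angles (0.6° step) on
  the ellipse, angle 0 at the anterior midline increasing toward
  subject-left, by bicubic interpolation at pixel-centre-aligned
  physical points. The ellipse is parameterised radially (ray–ellipse
  intersection), so an angular landmark means the same direction
  whatever the axis ratio.
* **Refinement.** Coordinate-wise pattern search over centre, semi-axes
  and tilt, maximising a profile-contrast objective: for each of the
  four quadrant windows, the trough of the smoothed profile scored
  against the mean of its two flanking white-matter sector peaks. Local
  flanks (not the global maximum) keep the optimum centred on a
  symmetric cord. Only gains above the relative tolerance (10⁻⁴) are
  accepted — sub-tolerance wiggles of an interpolated objective must not
  walk a symmetric solution off centre — and the search region is
  anchored to the moment ellipse (centre ±0.15 mm, axes ±10 %, tilt
  ±5°), because the moments are already the most robust estimate and an
  unconstrained contrast search drifts onto the cord/CSF boundary where
  interpolation overshoot inflates apparent contrast. Re-refining a
  refined ellipse is a fixed point (the anchor travels with the result).
* **Landmarks.** The midline minimises the left–right asymmetry of the
  smoothed profile (search ±30° around anterior); the transversal line
  is the direction of maximal cord-mask width through the mask centroid
  (plateau centre, since pixelation flattens the maximum); the
  posterior-horn exit angles are the deepest gray-matter troughs on each
  posterior side, refined to the centroid of the trough region below a
  depth threshold — partial volume flattens the troughs, so a raw argmin
  wanders under noise while the centroid stays put. A trough must be at
  least 0.05 FA deep; a cord without gray-matter contrast raises a
  landmark failure instead of latching onto numerical wiggles. By
  default the two horn angles are reported as a symmetric ± pair about
  the midline (deviations averaged), matching the butterfly model and
  halving the angular noise; fully independent detection is available
  for visibly asymmetric cords.
* **ROIs.** Six circles of 1.05 mm diameter, centres on the ellipse,
  snapped to the fine grid (21 pixels each on the 0.2 mm grid): dorsal
  columns at 0.15 of the arc from the posterior midline toward each horn
  (they hug the posterior median sulcus; staying clear of the horn
  wedge limits partial volume), pyramidal tracts midway between each
  horn and the transversal line, anterior horns at the anterior-quadrant
  profile troughs. Both arc fractions are configurable, as is a fully
  manual ellipse for expert override.

## The digital phantom

`phantom_spec()` describes a C2-like axial slice: 128 × 128 matrix over
a 100 × 100 mm² field of view (0.78125 mm pixels), 5 mm thick, an
elliptical cord (semi-axes 6.5 × 4 mm — a 13 × 8 mm C2 cord) inside a
1.6 mm CSF ring, and a mirror-symmetric butterfly gray matter: two
posterior-horn wedges exiting at ±35° from the posterior midline
(constant width 1.4 mm by default — a tapered wedge is purer at its
base, which drags the apparent exit angle under partial volume and makes
the angular ground truth ill-defined; taper remains configurable), two
anterior-horn blobs at ±33°, and a central commissure. White matter is
partitioned into dorsal column, lateral column (PT), anterior column and
anterolateral sectors. The construction uses only the unsigned lateral
offset, so the label map equals its mirror image exactly.

Tissue tensors default to healthy-control axial/radial diffusivity
pairs: 0.58/0.16 (PT and other white matter), 0.58/0.15 (dorsal
column), 0.42/0.22 (gray matter, eigenvalue FA ≈ 0.38), isotropic 3.0
for CSF, all ×10⁻³ mm²/s, principal axis along the cord. Note the
eigenvalue FA of the PT assignment is 0.675 — higher than typical
ROI-mean FA values (~0.54) of real cohorts, which average per-pixel FA
over partial-volumed tissue rather than pure-tissue eigenvalues.

Signals are rasterised on a 4× supersampled grid and box-averaged, so
boundary pixels carry partial-volume mixtures while interior pixels stay
pure (`supersample = 1` gives hard edges, used by the exact-recovery
tests). Per-volume anterior–posterior displacement is applied by
spectral translation (exact sub-pixel ground truth), then Rician noise:
the stored image is the average of `n_averages` magnitudes
`√((S+e₁)² + e₂²)` with `e ~ N(0, S0_wm / snr)`. The default of 16
averages reflects the multi-minute cardiac-triggered acquisition of
seven single-slice volumes, which acquires each volume many times; at
single-shot SNR 20 and no averaging, the 7-volume fit's eigenvalue noise
is ~50 % of the radial eigenvalue and no ROI statistic is stable, which
contradicts the measurement precision such protocols demonstrably reach.
"SNR 20" in the validation below therefore means snr = 20 per shot with
default averaging (effective b0 SNR ≈ 80).

What the phantom does **not** emulate: susceptibility and eddy-current
distortion, cardiac-cycle CSF pulsation, in-plane rotation or
left-right motion, coil shading, vertebral anatomy, or multi-slice
geometry. Passing phantom tests therefore demonstrates the correctness
and noise behaviour of the processing chain under idealised
single-slice EPI-like conditions, not robustness to artifacts the
phantom does not contain.

`simulate_cohort()` generates subject-level ROI-mean tables directly
from stated group moments (per region × metric), with left/right values
as the subject value ± a small side deviation so their mean reproduces
the drawn value exactly, plus demographics: control ages uniform over
20–65, patient ages normal around 48 truncated to the same range, sex at
the published group frequencies, SPRS ~ N(17.9, 8.5) truncated positive
for patients only.

## Statistics layer

All standard machinery is delegated: Levene's test is the mean-centred
classic (one-way ANOVA on absolute deviations via `lm`/`anova`, with
the median-centred variant one argument away), gating `t.test()` with
pooled or Satterthwaite df; `chisq.test(correct = FALSE)` for 2 × 2
tables; `wilcox.test(exact = FALSE)` for the Mann–Whitney comparison;
`lm()` plus emmeans for the age/sex-adjusted group model, with Cohen's
d = ΔEMM / residual SD (marginal means at the mean age, sexes balanced)
banded at 0.20/0.50/0.80. When covariates carry no variation they are
dropped and the result reduces exactly to the pooled t-test and classic
pooled-SD d. The Bonferroni family defaults to the three regions
compared per metric (the family an analysis of this design implies;
configurable). Missing clinical values are handled by listwise deletion
per analysis. Axial diffusivity is quantified per subject but excluded
from the group battery: single-slice axial acquisitions scatter AD too
widely for meaningful comparison.

Two simulation facts established during development (1000 replicates
each) are worth recording. First, the mean-centred Levene test at
sd 0.03 vs 0.04 with n = 115/32 has power 0.471 — a coin flip, not a
reliable gate, which is why both branches of the t-test dispatch are
tested directly. Second, for the dorsal-column FA moments (Δ = 0.04)
the variance-gated test yields p < 0.001 in 95.4 % of seeds, not ≥ 99 %:
whenever Levene correctly detects the variance difference, Welch's
larger standard error and smaller df lose just enough power. The
corresponding acceptance check is asserted at the stricter published
form and is expected to fail on the dorsal-column half; the test suite
documents rather than hides this.

## Validation summary and problem sizes

The test suite builds every fixture in code. Sizes were chosen so the
full suite runs in about a minute: full 128 × 128 phantoms where
geometry matters, 64 × 64 phantoms at the same pixel size elsewhere; 50
noisy phantoms for the ROI-recovery property (at snr 20: |FA error|
< 0.05 in ≥ 90 % and |RD error| < 0.03 ×10⁻³ mm²/s in ≥ 90 % of
region-cases, both asserted); 2000 replicates for the type-I error of
the variance-gated test (within [0.03, 0.07] at α = 0.05); 100–200
replicates for the remaining simulation checks. Noiseless properties
are exact: tensor recovery to 10⁻¹², left/right ROI-mean symmetry to
machine precision, horn angles within 3° (typically < 0.5°) of truth.

## Known limitations

* Landmark quality degrades gracefully but noticeably below effective
  b0 SNR ≈ 40; QC flags (landmark failure, shift at search bound,
  clamped-pixel fraction) are emitted for exclusion decisions rather
  than silent repair.
* The transversal-line search assumes the cord's widest axis lies
  within ±30° of perpendicular to the midline.
* Gradient directions are interpreted in the scanner frame assuming an
  axial slice with identity in-plane rotation; oblique acquisitions are
  out of scope.
* The pipeline is single-slice by design: no slice-to-slice
  registration, no tractography, no multi-shell models.
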