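# cordDTI

Column-specific diffusion tensor imaging (DTI) of the cervical spinal
cord from a single axial slice, with a digital cord phantom for
validation.

## The problem

Degenerative motor-neuron diseases such as hereditary spastic paraplegia
(HSP) damage the long fiber tracts of the spinal cord — the pyramidal
tracts (PT), and often the dorsal columns (DC) — in ways conventional MRI
cannot quantify. A high-resolution axial DTI slice at the C2 vertebral
level can resolve the individual white-matter columns and the
butterfly-shaped gray matter, but three obstacles stand between the raw
acquisition and usable per-column numbers: breathing displaces the cord
along the anterior–posterior axis between volumes; the cord is only a
dozen pixels across, so region placement must be geometric, not
freehand; and no public single-slice cord DWI data exist for validating
a processing chain.

cordDTI implements the full post-processing pipeline for such
acquisitions, and a synthetic phantom with known ground truth so that
every stage is testable without any download.

## The method

For each subject (one b0 volume plus six diffusion-weighted volumes,
encoding directions e1 = (1,0,1), e2 = (−1,0,1), e3 = (0,1,1),
e4 = (0,1,−1), e5 = (1,1,0), e6 = (−1,1,0), z along the cord):

1. **Crop** to the intraspinal space at the outer margin of the bright
   CSF ring on the b0 image (Otsu threshold + largest connected
   component), or with a manual box.
2. **Motion-correct** each weighted volume against the b0 using
   midsagittal intensity profiles (anterior–posterior axis only;
   spectral sub-pixel translation). No eddy-current correction is
   applied.
3. **Fit the diffusion tensor** per pixel by log-linear least squares —
   with 7 volumes the system `ln S = ln S0 − b gᵀDg` is exactly
   determined — and derive the scalar maps AD = λ₁, RD = (λ₂+λ₃)/2,
   MD = (λ₁+λ₂+λ₃)/3 and
   FA = √(3/2)·√Σ(λᵢ−λ̄)² / √Σλᵢ².
4. **Interpolate** the metric maps to a 0.2 × 0.2 mm² grid (bicubic).
5. **Segment** semi-automatically: fit a sampling ellipse to the cord on
   the FA map, read the FA along it at 600 angular samples (0.6° step),
   refine the ellipse by maximising gray/white profile contrast, and
   detect the midline, the transversal line, and the posterior-horn exit
   angles as the gray-matter troughs of the profile.
6. **Place six circular ROIs** (1.05 mm diameter, 21 pixels on the fine
   grid): PT, DC and anterior horn (AH), left and right, at angular
   positions derived from the landmarks, and report their means for
   FA/MD/RD/AD.

The cohort layer reproduces the statistics battery used for such
studies: Levene's test gates Student vs Welch comparisons, Bonferroni
correction across the three regions, Cohen's d from age/sex-adjusted
estimated marginal means (|d| bands 0.20/0.50/0.80), chi-square and
Mann–Whitney demographics tests, and linear/quadratic regression against
clinical scores (SPRS, age of onset, disease duration).

## Worked example

```r
library(cordDTI)

spec  <- phantom_spec(snr = 20, seed = 11)   # C2-like slice, noisy
truth <- make_cord_geometry(spec)
dwi   <- simulate_dwi(truth)
dwi
#> <dwi_slice: 128 x 128 px, 7 volumes, 0.7812 x 0.7812 mm, thk 5 mm>

res <- run_subject(dwi, id = "s11")
res$ellipse
#> <cord_ellipse: centre (8.39, 10.91) mm, axes 4.48 x 2.62 mm, tilt 4.8 deg>
#>   landmarks: midline 0.0, transversal 90.0, horns 146.3 / 213.7 deg
round(res$roi_means[c("PT_FA_L", "PT_FA_R", "DC_FA_L", "DC_FA_R")], 3)
#> PT_FA_L PT_FA_R DC_FA_L DC_FA_R
#>   0.707   0.676   0.678   0.697
```

The detected horn angles (146.3°/213.7°) sit within 1.3° of the phantom
truth (145°/215°), and the PT/DC FA means are within a few hundredths of
the assigned tissue values (eigenvalue FA 0.675 for PT, 0.696 for DC).
Cohort statistics on a synthetic cohort drawn at published
healthy-control and patient group moments:

```r
tab <- simulate_cohort(published_group_moments(), seed = 42)
battery <- cohort_battery(tab)
battery[battery$metric == "FA", c("region", "method", "mean_HSP", "mean_HC",
                                  "p", "p_adj", "cohens_d", "d_band")]
#>   region    method mean_HSP mean_HC        p    p_adj cohens_d     d_band
#> 1     PT Student t    0.493   0.537 1.04e-11 3.11e-11  -1.4247      large
#> 2     DC Student t    0.525   0.562 3.92e-08 1.18e-07  -1.1274      large
#> 3     AH Student t    0.374   0.373 9.19e-01 1.00e+00   0.0192 negligible
```

The pattern — strong FA reduction in the pyramidal tracts and dorsal
columns, none in the anterior horns — is the column-specific signature
of upper-motor-neuron tract degeneration this pipeline is built to
detect.

A thin command-line front end is installed with the package
(`inst/cli/cord-dti`) with `phantom`, `run`, `cohort` and `stats`
subcommands.

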