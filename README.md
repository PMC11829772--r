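# bmmech

Quantitative analysis of basement-membrane mechanics in *Drosophila* egg
chambers, for researchers working with AFM force-volume scans and
fluorescence images of the follicle epithelium. The package implements the
full measurement chain used to characterize how the basement membrane of
the egg chamber differs between a control genotype, a *fat2* allele
lacking its WIRS motifs, and a *fat2* null — and ships a synthetic-data
generator that emulates all three genotypes, so every stage is testable
without proprietary microscope data.

## What it computes

**AFM force-volume analysis.** Each pixel of a scan is one approach curve
F(z). The surface height is the deflection-corrected tip position where
the force crosses 20% of the 0.6 nN setpoint; the effective Young's
modulus comes from the Hertz-Sneddon model for a quadratic pyramidal tip,

    F = b · E/(1 − ν²) · tan(α) · δ²,

with half-angle α = 35°, Poisson ratio ν = 0.5, pyramid coefficient
b = 0.7453, and indentation δ = (z − z_c) − F/k corrected for cantilever
deflection (k = 0.03 N/m). The fit is linear in the prefactor on δ² over
forces up to 500 pN (≈ 200 nm indentation at the control stiffness).

**Map processing.** 3rd-order plane fitting and 1st-order line levelling
of topography, median + 2D Savitzky-Golay smoothing, 5×5 µm² region
medians, Pearson correlation between topography and stiffness maps, and
quantification of the Collagen-IV-like stripes of elevated stiffness
(elevation over bulk, segment lengths, orientation relative to the
anteroposterior axis).

**Fourier topography profiles.** Unnormalized 2D DFT, amplitude profile
along the fast axis against the inverse wavelength v/L, and pooling of
profiles from maps of different sizes onto a common 20 µm grid.

**Morphometry.** Structure-tensor orientation distributions over
[0°, 180°), the nematic order parameter relative to the AP axis
S_AP = Σ f(θ)·cos(2(θ − 90°)) (+1 perpendicular, −1 parallel, 0
isotropic), fiber lengths by skeletonization, and egg-chamber aspect
ratios from second moments.

**Rotation kinematics.** Angular velocity from matrix-trail geometry,
ω = (trail length / circumference) · 360°/t, and ex vivo rotation
velocity by polar cross-correlation registration of frame pairs.

**Center-to-pole ratio test.** R = mean(center)/mean(pole) with
error-propagated SEM, T = (R − 1)/SEM_R referred to a two-tailed t
distribution with Welch-Satterthwaite effective degrees of freedom.

## Worked example

```r
library(bmmech)

geom  <- scan_geometry(side_length = 10, n_pixels = 64)
truth <- gen_truth_fields(genotype_presets("control"), geom, seed = 1)
fv    <- gen_force_volume(truth$stiffness, truth$topography,
                          probe_params(), force_noise_sd = 10, seed = 2)
fit   <- fit_force_volume(fv)
region_median(smooth_map(fit$stiffness), square_side = 5)
#> [1] 19.84467

wide <- gen_truth_fields(genotype_presets("control"),
                         scan_geometry(20, 128), seed = 3)
quantify_stripes(wide$stiffness)
#> <stripe_stats> 28 stripes, elevation 9.42%, orientation 90.6 deg, fraction 0.131

angular_velocity(gen_trail(82, duration = 10, circumference = 300))
#> [1] 82
```

The region median recovers the 20 kPa control bulk stiffness from 4096
noisy curves; the stripe summary reports stiffness stripes ~10% above
bulk, oriented perpendicular to the AP axis (90°); the trail closed form
returns the control rotation rate in deg/h.

## Analysis workflow

The `analysis/` scripts rebuild the study's result tables end to end,
writing CSVs under `results/` (intermediate images and force volumes go
to `scratch/`, which is regenerable):

```sh
Rscript analysis/01_simulate.R      # synthetic scans, images, masks
Rscript analysis/02_forcefit.R      # per-pixel moduli, region medians
Rscript analysis/03_maps_stripes.R  # stripes, topography correlation
Rscript analysis/04_fourier.R       # pooled topography spectra
Rscript analysis/05_morphometry.R   # S_AP, fiber lengths, aspect ratios
Rscript analysis/06_kinematics.R    # trail + ex vivo rotation velocities
Rscript analysis/07_ratio_stats.R   # center-to-pole ratio tests
```

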