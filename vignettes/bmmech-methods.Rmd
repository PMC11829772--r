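---
title: "Models and methods behind bmmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bmmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bmmech)
```

bmmech implements the measurement chain for basement-membrane mechanics
of *Drosophila* egg chambers: AFM force-volume fitting, map processing
and stripe quantification, Fourier topography profiles, fiber
morphometry, rotation kinematics, and the center-to-pole stiffness-ratio
test. This vignette explains each model, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## The contact model and its parameters

An AFM approach curve records force against piezo extension. Past
contact, a quadratic pyramidal tip indenting an incompressible elastic
half-space follows

$$F = b \, \frac{E}{1-\nu^2} \tan(\alpha)\, \delta^2 ,$$

with tip half-angle $\alpha$ (35° for the probes modelled), Poisson ratio
$\nu = 0.5$, and indentation $\delta = (z - z_c) - F/k$, where the $F/k$
term removes the cantilever's own deflection ($k$ = 0.03 N/m nominal;
the calibrated value should be used with real data). The pyramid
geometry coefficient defaults to the four-sided-pyramid value
$b = 0.7453$; the cone coefficient $2/\pi \approx 0.6366$ is an accepted
alternative, and the two differ by ~8% in $E$ — within the spread of the
other calibration uncertainties. `probe_params()` exposes all of these.

Units are pN, nm and kPa throughout; the prefactor is
$C = b\,\tan(\alpha)\,E/(1-\nu^2) \times 10^{-3}$ pN/nm², so 20 kPa gives
$C \approx 0.0139$ and an indentation of ~190 nm at 500 pN.

### Two contact points, on purpose

Two different "surface positions" serve two different purposes:

* **Topography** uses the deflection-corrected tip position at which the
  force first crosses 20% of the setpoint (0.12 nN), linearly
  interpolated between samples. This threshold rule is robust to noise
  but systematically sits $\sqrt{0.2\,F_{set}/C}$ (~90 nm at 20 kPa)
  past the true contact — and that offset depends on the local stiffness.
* **Modulus fitting** needs the true contact. Because
  $\sqrt{F}$ is exactly linear in tip position under the quadratic
  model, an ordinary least-squares line through
  $(x, \sqrt{F})$ for forces between 10% of the setpoint and the 500 pN
  fit bound yields the contact position exactly for noiseless curves.
  The modulus then comes from the closed-form linear fit of $F$ on
  $\delta^2$ (`fit_hertz_sneddon()`), which recovers $E$ to machine
  precision in the zero-noise round trip and to ~1% (median over
  thousands of curves) at 10 pN force noise.

`fit_force_volume()` therefore returns both surfaces. For
topography–stiffness correlation analyses the fitted-contact surface
(`topography_contact`) is the right one: the threshold surface's
stiffness-dependent offset otherwise leaks the stiffness map into the
topography map and biases the correlation toward zero.

### Baseline

The force baseline is the median over the first quarter of the approach
(the free tail before contact). Selecting baseline samples by *position*
matters: taking the median of the lowest-*force* samples instead picks
the lower tail of the noise distribution and biases the baseline by
about $-0.5\sigma$, which propagates to a several-percent modulus error.
The fit range choices (20% threshold, 10%–500 pN window) assume curves
with a clean pre-contact tail of at least ~25% of samples.

## Map processing

**Levelling.** Topography maps carry scanner tilt/bow and per-line
offsets. `level_topography()` removes a total-degree-3 bivariate
polynomial and per-fast-axis-line linear trends. The two fits are
alternated to convergence, which makes the combined operation a true
projection: levelling an already-levelled map changes nothing (a single
poly-then-line pass is not exactly idempotent because the $x^2$-type
terms are not orthogonal to the per-line span). The output mean is set
to zero; whether line levelling should preserve means or medians is not
determined by the data, and the zero-mean convention is adopted.

**Smoothing.** A 3-pixel median filter removes single-pixel outliers,
then a 5-pixel order-2 two-dimensional Savitzky-Golay filter (a
least-squares polynomial surface per window, applied as a linear kernel)
smooths while passing constants, ramps and quadratics unchanged. Edges
are handled by reflection. The windows are chosen to preserve features
at the stripe scale (~1 µm) on a ~156 nm pixel grid.

**Region medians.** Stiffness summaries are medians over a 5×5 µm²
axis-aligned square (map centre by default). With stripes occupying
~20% of pixels at +10%, the region median sits ~2% above the bulk
median — well inside the comparison tolerances used downstream.

## Stripe quantification

The Collagen-IV-like stripes are faint: ~7–10% stiffness elevation
against 20% pixel-to-pixel noise. Three design elements make their
quantification reliable; all were chosen because simpler estimators are
measurably biased on synthetic ground truth.

1. **Leave-self-out segmentation.** Candidate stripe pixels are those
   above the 75th percentile of a directional Gaussian smoothing
   (σ = 1.5 µm along the expected stripe direction, perpendicular to
   the AP axis) computed *excluding each pixel's own value* and with
   zero-padded, renormalized borders. Thresholding a field that
   contains the pixel's own value selects pixels for their own noise:
   on a stripe-free field that alone fabricates a ~6% apparent
   "elevation". For the same reason `quantify_stripes()` expects the
   unsmoothed map — pre-smoothing correlates neighbouring pixels and
   reintroduces the bias through the neighbourhood.
2. **A band-structure detection test.** Stripes recur along the
   across-stripe axis. The across-stripe profile of bin means is tested
   against spatial homogeneity with a chi-squared variance test (exact
   under pixel-independent noise); maps compatible with a flat profile
   (p ≥ 0.01) are reported as stripe-free. This is what lets the
   stripe-free genotype come out clean instead of yielding percentile
   artefacts. Candidate components are additionally filtered by
   elongation (≥ 2), length (≥ 2 µm) and membership of a detected band.
3. **Mixture-amplitude elevation.** The measured band amplitude is
   $a = e \cdot \phi$ where $e$ is the stripe elevation and $\phi$ the
   along-stripe fill fraction (stripes are broken into segments). The
   amplitude comes from band-core versus far-bulk bin means (precise
   and selection-free); $\phi$ is fitted by matching the empirical CDF
   of the along-band profiles to a two-level Gaussian mixture with
   known noise scale under the constraint $e\phi = a$; the reported
   elevation is $a/\phi$. Direct medians over the segmented mask are
   diluted by gap and edge pixels and under-read the elevation by 2–3
   percentage points at these SNRs.

On synthetic ground truth (20 µm, 128² px maps) the estimator is
unbiased with a seed-to-seed spread of ~0.6 percentage points for long
stripes and ~0.9 for short ones. Segment lengths are reported as
$\sqrt{12}\,\sigma_{major}$ of each final component (exact for a uniform
bar); orientations are area-weighted axial means.

## Fourier profiles

`dft2()` computes the unnormalized forward 2D DFT (the `stats::fft`
convention, validated against a brute-force double sum and by
Parseval's identity in the tests). The x-direction profile aggregates
|F(u,v)| by the *mean* over u and reports v = 0..N/2 against the inverse
wavelength v/L; mean versus sum changes only a constant factor, and only
profile shapes are compared. Maps are cropped to the largest centred
defect-free square before transforming. Profiles from maps smaller than
the 20 µm reference are linearly interpolated onto the reference grid
before pooling (mean ± SEM). No windowing is applied; conclusions are
drawn from band-wise comparisons between genotypes, not from absolute
amplitudes.

## Morphometry

Orientations come from the smoothed structure tensor (gradient scale
1 px, tensor scale 2 px): the local fiber direction is the tensor's
minor eigenvector, histogrammed over [0°, 180°) in 2° bins weighted by
gradient energy. Energy weighting (rather than equal weighting of all
pixels) concentrates the histogram on actual structures; this is a
choice, and it slightly emphasizes bright fibers. The order parameter

$$S_{AP} = \sum_\theta f(\theta) \cos(2(\theta - 90^\circ))$$

is the standard 2D nematic order parameter referenced to the axis
perpendicular to the AP axis, the unique cosine form with value +1 for
perpendicular alignment, −1 for parallel, and 0 for isotropy.

Fiber lengths use global thresholding (Otsu or quantile), Zhang-Suen
thinning, pruning of spurs shorter than 3 px, and 8-connected chain
length (1 per orthogonal link, √2 per diagonal — exact for axis-aligned
and 45° chains, up to ~8% high in between). In dense fields crossing
fibers merge into one skeleton and the measurement reflects connected
paths rather than single fibers; length comparisons should use sparse
fields or be read as relative. Aspect ratios are
$\sqrt{\lambda_1/\lambda_2}$ of the mask's second-moment ellipse
(+1/12 px² discretization correction), which equals major/minor exactly
for solid ellipses and is rotation invariant.

## Kinematics

Trail records convert directly:
ratio = 100·length/circumference (wrapping trails exceed 100%) and
ω = ratio·360°/(100·t). The ex vivo estimator resamples both frames to
polar coordinates about the chamber centre (radii 0.35–0.95 R, 720
angular samples), removes per-radius means, and finds the circular
cross-correlation peak over angular shifts with quadratic sub-bin
interpolation; velocity = angle·R/dt. A normalized peak below 0.2 is
reported as "not detected" rather than as a velocity. The estimator is
antisymmetric under frame exchange and recovers synthetic rotations to
well within 5%.

## The ratio test

For per-chamber stiffness summaries (the pipeline uses per-chamber 5×5
µm medians, then cross-chamber means),

$$R = \frac{\bar{x}_c}{\bar{x}_p}, \qquad
  \mathrm{SEM}_R = R\sqrt{\left(\tfrac{\mathrm{SEM}_c}{\bar x_c}\right)^2
  + \left(\tfrac{\mathrm{SEM}_p}{\bar x_p}\right)^2},$$

and $T = (R-1)/\mathrm{SEM}_R$ is referred to a two-tailed t
distribution with Welch-Satterthwaite effective degrees of freedom
computed from the two relative variance components
$a_i = \mathrm{SEM}_i^2/\bar x_i^2$:

$$\nu_{eff} = \frac{(a_c + a_p)^2}{a_c^2/(n_c-1) + a_p^2/(n_p-1)},$$

which reduces exactly to $2(n-1)$ for symmetric inputs. The t CDF is
evaluated at non-integer degrees of freedom. Under a matched null
(equal-mean lognormal samples, CV 0.2, n = 8 + 8) the empirical type-I
error at α = 0.05 is within ±0.01 of nominal (10,000 replicates). The
delta-method SEM makes the test slightly approximate for very skewed
samples or tiny n; degenerate inputs (zero SEM) are flagged rather than
silently producing p values.

Group comparisons use Welch's t-test, the Wilcoxon rank sum test (exact
enumeration below n = 8 per group, normal approximation without
continuity correction otherwise), or a one-sample t-test against zero
(for per-chamber correlation coefficients).

## The synthetic generator: what it emulates, and not

The generator's defaults are the study conditions. Three genotype
presets carry the genotype-level magnitudes: control (bulk 20 kPa, 10%
stripes of length 8 µm, topography-stiffness correlation −0.4,
center:pole ratio 1.3), ΔWIRS (11 kPa — a 45% reduction, 7% stripes of
length 2.5 µm, no correlation, ratio 1.25) and fat2 null (7 kPa — a 70%
reduction, no stripes, no correlation, ratio 1.0). Scan geometry
follows the instrument: 5–20 µm squares at 128 or 180 points per side,
AP axis along the fast axis; probe parameters as above; 0.6 nN setpoint.

Free choices the study does not pin down, set once to realistic values:
stripe width 1.25 µm and spacing 5 µm (fiber-scale features at ~20%
areal coverage), 1 µm gaps between segments, lognormal pixel noise with
CV 0.2, topography amplitude 30 nm with a 0.8 µm correlation length for
the smooth component, polynomial tilt of ~40 nm per normalized-coordinate
term, per-line offsets of 5 nm and slopes of 2 nm. Stripe edges are
softened by only a sub-pixel blur (σ = 0.35 px): wider blurs would make
the realized stripe-pixel elevation fall short of the nominal preset for
short segments. The topography's independent component mixes white and
smooth parts in the same variance proportions as the stiffness field, so
the built-in correlation survives the common smoothing applied to both
maps; the correlation itself is imposed exactly by orthogonalized mixing.
Force volumes include a 150 nm free-approach tail so the baseline window
is clean at every pixel.

What the generator does **not** emulate — and hence what passing tests
do not demonstrate about real data: viscoelasticity, adhesion, thermal
drift and lateral tip convolution in the force curves; spatially
correlated instrument noise; curved chamber geometry (maps are flat);
photorealistic confocal texture, out-of-focus light or stage-dependent
fiber morphologies; and any biology beyond the summary magnitudes listed
above. Parameter recovery on this generator validates the estimators'
correctness and calibration, not the microscope physics.

## Problem sizes

The shipped tests and scripts run on deliberately moderate sizes chosen
to exercise every code path at full fidelity: 64×64-curve force volumes
(4096 curves, 2 nm z-step), 128² stripe maps, 10,000-replicate null
calibrations, 720-bin polar registration. All are deterministic given
the documented seeds.
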