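---
title: "Ratiometric two-photon analysis of enzyme-activity probes: models and methods"
author: "tpmRatiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric two-photon analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmRatiometry)
```

## The measurement

Ratiometric two-photon probes shift their emission from a short-wavelength
band (Ch1, 400–450 nm) to a long-wavelength band (Ch2, 600–650 nm) when
converted by their target enzyme. The Ch2/Ch1 intensity ratio therefore
reports enzymatic activity independently of probe concentration, staining
depth and excitation power — the quantities that vary uncontrollably in
thick tissue. The panel analyzed here is

* **SG1** — β-galactosidase; activity (and so the ratio) is *higher* in
  gastric cancer tissue than in normal mucosa,
* **SE1** — carboxylesterase; activity is *lower* in cancer, so the ratio
  direction is inverted,
* **SHC** — hNQO1; no usable cancer/normal separation in stomach.

A sample is a two-channel z-stack of optical sections acquired over the
80–200 µm depth range. The pipeline computes a per-voxel ratio volume, a
whole-depth sample mean ratio, a per-section depth profile, pseudocolor
renderings, and group statistics over a cohort; a plate-reader lysate
time-course arm cross-validates the imaging readout on homogenized tissue.

## Calibrations

`imagingCalibrations()` and `lysateCalibrations()` store, for each probe
and tissue class (normal, ulcer, adenoma, cancer), the group mean ratio
and between-sample SD measured on the clinical cohort (n = 21/18/17/20,
total 76). They serve two roles: they parameterize the synthetic cohort
generator, and they supply display ranges and classifier directions. The
± values are treated as *between-sample* SDs — the per-group spread of
per-sample means — not as within-sample voxel noise; within-sample spatial
heterogeneity is a separate generator knob (below).

One direction flag deserves emphasis: in the lysate arm the SE1 endpoint
is **1.313 in cancer versus 1.859 in normal** — cancer *below* normal,
consistent with reduced carboxylesterase activity in cancer and with the
imaging direction. Code that assumes "cancer value first, and larger"
will silently invert SE1; `probeDirection()` encodes the correct side per
probe.

## The synthetic tissue generator

Raw clinical stacks are not deposited, so validation rests on a generator
whose defaults *are* the study conditions.

**Per-sample mean.** `buildPhantom()` draws the sample's mean ratio from
Normal(µ_class, σ_class), truncated at zero, using the calibration for
the requested probe and class.

**Spatial texture.** The true per-voxel ratio field is the sample mean
plus `textureSd` (default 0.05, ratio units) times a smooth unit-variance
Gaussian random field (white noise smoothed laterally with a σ = 4 px
kernel and mildly along z), floored at 0.01. The default is a free
choice — within-sample heterogeneity of enzyme activity is not quantified
in the source data — set so per-sample voxel spread is visible but small
against the between-class differences.

**Gland geometry.** Gastric glands are modelled as tubules: bright
annular walls (relative brightness 1) around a dark lumen, on a
hexagonal-offset lattice extruded in z with sub-pixel per-section jitter;
background brightness is 0.02. `disorder` ∈ [0, 1] displaces tubule
centres (SD = disorder·spacing/3) and perturbs radii (±40 %·disorder);
0 reproduces a periodic lattice, and the class defaults are 0.05 (normal),
0.2 (ulcer), 0.3 (adenoma) and 0.6 (cancer), so normal phantoms show the
regular gland pattern and cancer phantoms the irregular, disordered one.

**Forward imaging model.** `renderStack()` splits a voxel's brightness
between the channels so the emission ratio is exact:

$$E[\mathrm{Ch2}] = B\frac{r}{1+r}, \qquad E[\mathrm{Ch1}] = B\frac{1}{1+r},
\qquad B = b \cdot N_0 \cdot e^{-z/\ell},$$

with $r$ the voxel's true ratio, $b$ relative brightness, $N_0$ the
photon budget (default 500 counts at the brightest surface voxel) and
$\ell$ the attenuation length (default 150 µm, a typical effective
signal-loss scale for two-photon imaging in scattering mucosa). Observed
counts are Poisson(E) plus Gaussian read noise (SD 1 count), rounded and
clipped to the 16-bit range. Channel conservation
(Ch1 + Ch2 = B, noise-free) and exact ratio recovery are asserted by the
test suite.

What the generator does **not** emulate: optical PSF blur and scattering
tails, spectral bleed-through between bands, autofluorescence, motion and
registration error, and any correlation between gland architecture and
enzyme activity. Passing tests therefore demonstrate that the *analysis*
recovers what the *model* encodes at realistic counting noise — not that
the model captures every property of real tissue.

**Depth range.** The acquisition default places 30 sections evenly over
80–200 µm. The source describes the imaged range both as 90–210 µm (in
the methods) and 80–200 µm (in the results); both are supported through
`AcquisitionParams(zPositions=, depthWindow=)` and the results-side
80–200 µm is used as the default, without privileging either as correct.
The per-sample section count is likewise not recoverable from the source;
30 sections is the package default.

## Ratiometry

`foregroundMask()` separates gland signal from background on the summed
Ch1+Ch2 intensity, by Otsu's threshold on the pooled volume histogram
(default) or a percentile cut. Voxels with Ch1 = 0 or Ch2 = 0 (ratio
undefined or zero) and voxels saturated at 65535 in either channel (ratio
biased) are always excluded. The masking procedure is this package's
construction — the original analysis does not state one — which is why it
is deterministic, simple, and validated against phantom ground truth
(≥ 99 % gland-voxel recovery at default settings).

`ratioMap()` divides the channels voxel-wise inside the mask. The map is
scale-invariant and is never clipped for statistics; the display range
only affects rendering.

`sampleMeanRatio()` averages per-voxel ratios over all masked voxels of
all sections in the depth window, each voxel weighted equally. This is
the *mean of ratios*, not the ratio of channel means: the ratio image is
computed first and then averaged, matching the sectional-image workflow,
and the two definitions differ under spatial heterogeneity. No
per-section reweighting is applied ("entire sample depth").

With 500-count budgets the per-voxel Poisson ratio estimate carries a
small positive bias (≈ 1/E[Ch1], about 1 % at depth). It is left
uncorrected: correcting it would break the exact voxel-wise definition of
the ratio, and the cohort-recovery tests show it is well inside the 2-SE
tolerances at study sizes.

`pseudocolor()` encodes ratio as hue over a blue→green→yellow→red ramp
clipped to the display range (default per probe:
[µ_normal − 2σ, µ_cancer + 2σ], endpoints sorted) and summed intensity as
brightness, with unmasked background black — so normal SG1 tissue renders
green-to-blue and cancer yellow-to-red, and the rendering is
concentration-independent.

## Depth profiles

`depthProfile()` reports mean/min/max/SD of the masked ratios per section
inside the depth window; error bars carry min/max (SD is stored
additionally). Sections are binned by exact z position — no
interpolation. `profileConsistency()` asserts, on every pipeline run, the
algebraic identity that the voxel-count-weighted mean of section means
equals the whole-sample mean to ≤ 1e-9 relative error; its failure
indicates an internal bookkeeping bug, never a data property.

## Cohort statistics

`compareGroups()` resolves the "t-test or rank-sum, as appropriate"
convention with an explicit, configurable gate: Shapiro–Wilk at α = 0.05
on both groups; both normal → Welch's unequal-variance t-test (group SDs
differ up to threefold, so a pooled test is not defensible); otherwise a
Wilcoxon rank-sum test, exact for small samples including a tie-aware
enumeration of the exact null when the pooled n is ≤ 20 (the stock
implementation approximates under ties). All p-values are two-sided.
No multiple-testing correction is applied across the probe × class-pair
grid by default (matching the unadjusted reporting convention);
`compareAllGroups(adjust = "bonferroni")` is available.

`fitThreshold()` builds a single-cutoff diagnostic rule by maximizing
Youden's J over midpoints between sorted sample means, with the calling
direction taken from the calibration (above-threshold calls cancer for
SG1, below for SE1). Cut-off selection is this package's construction —
the study defers clinical cut-offs to larger cohorts — and is provided
for training-set characterization only; ties at the threshold are called
non-cancer, the conservative side.

## Lysate kinetics

The time-course model is a first-order approach to plateau,
$R(t) = R_\infty - (R_\infty - R_0)e^{-kt}$, sampled every 10 min over
0–120 min. The source shows trajectories but fits no model; first-order
conversion is the natural minimal kinetics for probe turnover at fixed
enzyme activity and is documented as a modeling choice. Generator
defaults: k = 0.03 min⁻¹ (trajectories approach plateau within the
2-hour window without saturating early), R₀ = 0.5 (unconverted-probe
baseline ratio, below every group endpoint), noise SD 0.02 per time
point. Per sample, the t = 120 endpoint is drawn from the endpoint
calibration and R∞ is solved so the noise-free endpoint equals the draw —
the generator is calibrated to endpoint statistics, which is also what
the analysis reads out (`endpointRatio()` takes the single t = 120 value,
matching one relative ratio per sample, rather than a window mean).

`fitFirstOrder()` recovers (R₀, R∞, k) by bounded Levenberg–Marquardt
least squares (k ≥ 0), initialized from the first point, the last point
and a log-linearized mid-course estimate of k. Flat series short-circuit
to k = 0 exactly; non-convergence is reported as a flagged result, never
an exception. Noise-free round-trips recover parameters to ≤ 1e-6
relative error; at noise SD 0.02 the median relative error on k is
within 10 %.

## Numerical and degenerate-input choices

* Truncated-normal draws use rejection sampling; σ = 0 degenerates to the
  mean exactly.
* All RNG consumption happens under `withSeed`-style scoping: generators
  never disturb the caller's RNG stream, and per-sample seeds are derived
  from the master seed by a deterministic hash of (probe, class, index),
  so cohorts are reproducible and per-group streams are decorrelated.
* An empty foreground mask, a depth window containing no sections, fewer
  than 2 samples per group, or a missing 120-min point are hard errors
  with diagnostics, not silent NAs.
* TIFF output refuses non-integral or out-of-range counts rather than
  rounding silently; readers refuse page-count mismatches and missing
  sidecar fields, because a silent channel swap would invert every
  probe's diagnostic direction.

## Problem sizes used in validation

The shipped validation suite simulates cohorts at the study's group sizes
(21/18/17/20) with 64 × 64 px × 30-section stacks for the parameter
recovery checks, 200 replicate cohorts at summary level for the
significance-pattern check, and 4 × 4 × 3 stacks for brute-force oracle
comparisons; these sizes are the package's validation design and are
asserted in `tests/testthat/test-acceptance.R`.

## Known limitations

* The phantom's texture SD, gland dimensions and attenuation length are
  plausible but not fitted to real images; only the group-level ratio
  statistics are calibrated.
* The mean-of-ratios estimator carries the small Poisson bias discussed
  above; at very low photon budgets (≪ 100 counts) it would grow and a
  bias-corrected estimator would be needed.
* Threshold classifier metrics are training-set (resubstitution) values;
  no external validation cohort exists inside the package.
* Depth profiles characterize activity versus depth; they do not attempt
  invasion-depth (pT) staging.
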