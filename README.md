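# tpmRatiometry

Quantitative analysis of **ratiometric two-photon microscopy** for
enzyme-activity-based tissue diagnosis, with a calibrated synthetic-tissue
simulator for validation.

Ratiometric probes shift emission from a short band (Ch1, 400–450 nm) to a
long band (Ch2, 600–650 nm) when converted by their target enzyme, so the
per-voxel **Ch2/Ch1 ratio** reports enzymatic activity independently of
probe concentration and imaging depth. For gastric tissue the probe panel
is SG1 (β-galactosidase, ratio rises in cancer), SE1 (carboxylesterase,
ratio falls in cancer) and SHC (hNQO1, non-discriminating). Given a
two-channel z-stack the package computes

* a foreground-masked per-voxel ratio volume
  (Otsu or percentile masking),
* the whole-depth **sample mean ratio**
  $\bar R = \frac{1}{|M|}\sum_{v \in M} \mathrm{Ch2}_v/\mathrm{Ch1}_v$
  over all masked voxels in the 80–200 µm window,
* per-section depth profiles (mean with min/max error bars),
* pseudocolor renderings (hue = ratio, brightness = intensity),
* cohort statistics: Shapiro–Wilk–gated Welch t / exact Wilcoxon rank-sum
  comparisons, fold changes, and a Youden-J threshold classifier,
* first-order kinetics fits
  $R(t) = R_\infty - (R_\infty - R_0)e^{-kt}$ and t = 120 min endpoint
  statistics for the plate-reader **lysate** cross-validation arm.

Because the clinical stacks are not publicly deposited, the package ships
a synthetic cohort generator (`buildPhantom()`, `renderStack()`,
`simulateCohort()`) whose defaults reproduce the study conditions:
gland-structured phantoms (regular lattices in normal tissue, disordered
in cancer), per-sample mean ratios drawn from the published per-class
calibrations, exponential depth attenuation, and Poisson + read noise.

## Worked example

```r
library(tpmRatiometry)

calib <- imagingCalibrations()[["SG1"]]
sim   <- simulateSample("cancer", calib, AcquisitionParams(),
                        seed = 42, sampleId = "demo01")
mask  <- foregroundMask(sim$stack)
rv    <- ratioMap(sim$stack, mask)
rv
#> RatioVolume 'demo01' (probe SG1): 34256 masked voxels, ratio 0.570-2.194 (mean 1.090)

sampleMeanRatio(rv)
#>   sample_id probe_id tissue_class mean_ratio n_foreground_voxels n_sections
#> 1    demo01      SG1       cancer   1.089726               34256         30
```

The sample's mean ratio (1.09) is a draw from the SG1 cancer-class
distribution (1.127 ± 0.109); 34k gland voxels over 30 sections entered
the mean. A simulated cohort at the study's group sizes separates cancer
from normal the same way the imaging readout does:

```r
s   <- simulateCohortSummaries("SG1", seed = 11)
cmp <- compareGroups(s, "SG1", "normal", "cancer")
cmp[, c("n_a", "n_b", "mean_a", "mean_b", "test_used", "p_value", "fold_change")]
#>   n_a n_b    mean_a   mean_b test_used      p_value fold_change
#> 1  21  20 0.6041059 1.142441    t-test 8.710939e-18    1.891127
```

i.e. a ~1.9-fold higher ratio in this replicate cohort (population fold
change 1.127/0.656 ≈ 1.72), overwhelmingly significant — while the same
comparison for SHC is not. `runSimulate()` / `runAnalyze()` /
`runCompare()` / `runLysate()` / `runReport()` chain these steps from a
single YAML config (`inst/scripts/tpm_pipeline.R` wraps them for shell
use).

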