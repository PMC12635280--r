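# tizmapr

Quantitative susceptibility mapping (QSM) pipeline for delineating a
**tumor and immune cell infiltration zone (TIZ)** in peritumoral edema.

Peritumoral edema around high-grade gliomas hides infiltrating tumor
cells and iron-laden macrophages that conventional MRI cannot see. Iron
makes tissue more paramagnetic; edema dilutes the diamagnetic myelin
matrix. `tizmapr` splits each voxel's magnetic susceptibility into a
paramagnetic component (PCS >= 0) and a diamagnetic component
(DCS <= 0) and forms the ratio

    PDR = PCS / |DCS|

as an infiltration marker. The TIZ is the set of edema voxels whose PDR
exceeds the maximum PDR of the trimmed contralateral gray matter, after
excluding tumor voxels dominated by blood (high nCBV from DSC
perfusion, high Ktrans from DCE permeability).

The package implements the full chain in R:

* **Phantom** — a mirror-symmetric digital tumor-brain phantom with
  ground-truth susceptibility sources, a planted infiltration pocket,
  multi-echo GRE signal (eight echoes, TE 5-40 ms, 3 T) and DSC/DCE
  dynamics, so every stage is testable without any data download.
* **QSM** — Laplacian phase unwrapping, eroded-brain + tumor analysis
  mask, weighted multi-echo field fit, V-SHARP background removal
  (multi-radius spherical mean value filter with model-based Tikhonov
  deconvolution), and two dipole-inversion algorithms (thresholded
  k-space division; Tikhonov-regularised conjugate gradients).
* **Decomposition** — constrained two-pool static-dephasing inversion
  of (chi, R2') into PCS/DCS with closed-form KKT projection.
* **Hemodynamics** — delta-R2* conversion, peak-ranked AIF selection,
  linear leakage correction, AUC-ratio CBV, contralateral-NAWM nCBV,
  VFA T1 mapping, SPGR concentration conversion, extended Tofts
  fitting, and the percentile-rule blood-exclusion mask.
* **PDR/TIZ** — PDR computation with an epsilon floor, per-tissue
  95th-percentile reference trimming, GM-max thresholding, TIZ
  segmentation, and Dice overlap between the two inversion algorithms.
* **Statistics** — exact/approximate Wilcoxon rank-sum, logPDR
  histogram features (median, Freedman-Diaconis mode, 10th
  percentile), Pearson correlations, and the iterative t-based Welch
  sample-size calculation.

## Worked example

```r
library(tizmapr)

res <- run_pipeline(default_config(seed = 11))

for (alg in names(res$tiz)) {
  tz <- res$tiz[[alg]]
  cat(alg, ": theta =", round(tz$threshold, 3),
      " n_tiz =", tz$tiz$n_voxels,
      " dice_vs_truth =", round(dice(tz$tiz$tiz_mask,
                                     res$phantom$truth$tiz_truth), 3), "\n")
}
cat("cross-algorithm dice:", round(res$dice_cross_algorithm, 3), "\n")
cat("TIZ vs contralateral GM, rank-sum p:",
    res$report$tests$tiz_vs_contralateral$p_value, "\n")
```

```
tkd : theta = 3.862  n_tiz = 464  dice_vs_truth = 0.714
iterative : theta = 2.933  n_tiz = 491  dice_vs_truth = 0.679
cross-algorithm dice: 0.882
TIZ vs contralateral GM, rank-sum p: 0
```

Reading the output: `theta` is the subject-specific TIZ threshold — the
maximum PDR remaining in the contralateral gray matter after trimming
values above the 95th percentile (subcortical nuclei removed). Every
edema voxel with PDR strictly above `theta` (and not excluded as
blood-dominated) joins the TIZ. On this phantom the recovered TIZ
overlaps the planted infiltration pocket with Dice 0.71, the two
independent dipole-inversion algorithms agree on the zone with Dice
0.88, and the TIZ PDR distribution separates from contralateral gray
matter with a rank-sum p below machine precision — by construction the
two ranges cannot overlap at all.

The sample-size question — how many subjects per group would an
*unpaired* comparison of median PDR in the TIZ versus contralateral
gray matter need — is answered by the iterative unequal-variance
calculation:

```r
welch_sample_size(86.29, 149.84, 1.04, 0.08, alpha = 0.05, power = 0.80)
#> [1] 27
```

## Command line

A thin CLI wraps the phantom generator and the full pipeline:

```sh
Rscript inst/cli/tizmap.R simulate --out phantom_dir --seed 7
Rscript inst/cli/tizmap.R run-all  --out run_dir --seed 7
```

Outputs are NIfTI volumes (float32; masks uint8) plus JSON report and
provenance sidecars recording every computed threshold.

See `vignettes/tiz-methods.Rmd` for the model assumptions, parameter
choices, numerical conventions and known limitations.
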