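---
title: "Mapping the tumor and immune cell infiltration zone from magnetic susceptibility sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the tumor and immune cell infiltration zone from magnetic susceptibility sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Peritumoral edema around high-grade gliomas is not passive fluid: part of
it is infiltrated by tumor cells and iron-laden immune cells
(tumor-associated macrophages). Conventional MRI cannot separate
infiltrated from purely edematous tissue. Iron accumulation makes tissue
more paramagnetic while edema dilutes the diamagnetic myelin matrix, so
the *composition of magnetic susceptibility sources* inside a voxel is a
candidate marker of infiltration. `tizmapr` implements a complete
pipeline that

1. reconstructs the total magnetic susceptibility map (QSM) from
   multi-echo gradient-echo phase,
2. splits each voxel's signal into a paramagnetic component (PCS, >= 0)
   and a diamagnetic component (DCS, <= 0),
3. forms the dimensionless ratio **PDR = PCS / |DCS|**,
4. delineates a **tumor and immune cell infiltration zone (TIZ)** as the
   edema voxels whose PDR exceeds the maximum PDR of trimmed
   contralateral gray matter,
5. excludes tumor voxels dominated by blood using DSC perfusion (nCBV)
   and DCE permeability (extended Tofts Ktrans) criteria, and
6. runs the associated statistics (rank-sum tests, logPDR histogram
   features, correlations, and a Welch-type sample-size calculation).

Because no clinical data ship with the package, a **symmetric digital
tumor-brain phantom** generates every input with known ground truth; all
properties of the pipeline are validated against that truth.

## The phantom: what it emulates, what it does not

The phantom is an ellipsoidal head (semi-axes 48 x 54 x 46 mm in a
128 mm field of view, 64^3 voxels at 2 mm isotropic) built exactly
mirror-symmetric about the mid-sagittal index plane: a 6 mm cortical
gray-matter band over a white-matter core, paired ventricles, paired
subcortical nuclei and paired arterial vessels. The symmetry is exact by
construction so that the contralateral-mirror logic of the method
(healthy reference regions obtained by flipping masks across the
midline) holds without registration. A one-sided tumor complex is
stamped into the right hemisphere: an edema shell (half-axes 18, 16,
16 mm) containing an enhancing rim (10 mm) and a necrotic core (5 mm).
The planted infiltration pocket (half-axes 8, 10, 10 mm, about 2 cm^3)
sits in the *medial* edema, against the enhancing rim: gliomas invade
preferentially along deep white-matter tracts toward the midline rather
than toward the cortex, and a pocket several voxels across keeps its
recovery from being dominated by voxel quantisation.

Every label carries a paramagnetic and a diamagnetic source
susceptibility (ppm). These values are **synthetic**: the ordering
WM < GM << TIZ on the PDR scale mirrors the qualitative contrast the
method relies on, but no measured tissue table is reproduced. The
infiltration pocket is strongly paramagnetic (0.15 ppm) and nearly
myelin-free (-0.005 ppm); edema is balanced (0.02 / -0.02 ppm); the
vessel carries *arterial* values (0.06 / -0.01 ppm) because its role is
to supply the arterial input function — venous blood would be far more
paramagnetic, but a venous vessel is not what a perfusion AIF samples.

The forward models are the ones the reconstruction assumes, which makes
recovery testable end to end:

* field: periodic convolution with the unit dipole kernel
  `D(k) = 1/3 - kz^2/|k|^2`, `D(0) = 0`;
* multi-echo signal: `S(TE) = m0 exp(-R2* TE) exp(i 2 pi f0 field TE)`
  with eight echoes at TE = 5 to 40 ms (dTE = 5 ms), 3 T, and
  `R2* = R2_base + kappa (PCS + |DCS|)` in the static-dephasing sphere
  regime, `kappa = (2 pi / 9 sqrt(3)) gamma_bar B0 1e-6` per ppm
  (about 51.5 s^-1/ppm at 3 T);
* complex Gaussian noise with SD `noise_sigma x m0_WM` per channel
  (default 0.02, i.e. SNR 50 at the first echo) — Rician magnitude bias
  is ignored, a high-SNR simplification;
* DSC: gamma-variate arterial bolus arriving at 45 s (TR 1.5 s, 120
  frames, TE 40 ms), tissue curves scaled by per-label blood volume,
  plus — in enhancing tumor only — a leakage term that is *exactly* the
  linear leakage-correction model, so the correction is testable by
  construction;
* DCE: extended Tofts tissue curves driven by a shared plasma input
  (gamma-variate first pass plus a recirculation plateau), SPGR signal
  at 15 degrees (TR 5 ms), 80 frames at 5 s, VFA baselines at 5/10/15
  degrees; relaxivity r1 = 3.6 /s/mM. No hematocrit correction is
  applied anywhere (the phantom vessel carries the plasma curve
  directly).

What the phantom does **not** emulate: real anatomy (no folded cortex,
no template brain), B0/B1 inhomogeneity, motion, partial-volume mixing
beyond voxel quantisation, Rician noise, and registration error
(volumes are born co-registered). Passing the phantom suite therefore
demonstrates the *internal consistency* of the pipeline — that each
stage inverts its forward model and that the TIZ logic recovers a
planted target under realistic noise — not clinical accuracy on
patient data.

## QSM chain

**Unwrapping.** Laplacian phase unwrapping solves
`lap(phi_u) = cos(phi) lap(sin phi) - sin(phi) lap(cos phi)` with a
spectral Poisson solve. The solution is defined up to a harmonic
component; with periodic boundaries that ambiguity is a constant, fixed
by returning a zero-mean volume. A consequence worth knowing: a pure
linear phase ramp is invisible to this operator (its right-hand side
vanishes identically), which is a property of the method, not a bug of
the implementation. The multi-echo field fit absorbs any such constant
per echo through its intercept.

**Analysis mask.** The brain mask is eroded by 3 mm (phase is
unreliable at the boundary) and the binarised tumor mask is added back
so cortex-adjacent tumor survives.

**Field fit.** A per-voxel weighted least-squares slope of unwrapped
phase against echo time (weights = squared magnitude, intercept
included) converted to ppm. Fitting one field across echoes (rather
than one susceptibility map per echo) is better conditioned at this
problem size; it is the package's default convention.

**Background removal (V-SHARP).** Harmonic fields generated by sources
outside the mask satisfy the spherical mean-value property and are
annihilated by the multi-radius SMV high-pass (radii 12, 8, 4, 2 mm;
each voxel is filtered with the largest sphere that fits). The
deconvolution that turns filtered residuals back into the local field
is Tikhonov-regularised (lambda = 0.05) and *model-based*: a source
distribution is estimated by conjugate gradients such that its dipole
field, passed through each radius's high-pass, matches the filtered
data on that radius's shell; the returned local field is the dipole
field of that source estimate. A plain spectral division of the
truncated filtered volume cannot recover the harmonic-inside-the-mask
part of the internal field (dipole tails of sources near the boundary);
parameterising through the dipole model restores it. Anti-aliased
(fractional-edge) sphere kernels reduce the discretisation error of the
spherical means at 2 mm resolution. The output support is the mask
eroded by the smallest radius.

**Dipole inversion, two slots.** The method's reproducibility argument
rests on comparing TIZ masks from two independent inversion algorithms.
Slot one is thresholded k-space division (TKD): divide by the dipole
kernel clamped at `sign(D) x 0.2`. Slot two minimises
`|W(D*chi - field)|^2 + lambda |grad chi|^2` (W = mask, lambda = 1e-2)
by conjugate gradients. Both are linear, deterministic, and
mean-centred over the mask (QSM is reference-free; comparisons are made
after de-meaning). Known behaviour: with the clamp at 0.2 the TKD
estimate of a uniform sphere's interior mean is biased low by roughly
18% — the interior field of a sphere is exactly zero, so all interior
information lives in the cone-adjacent frequencies the clamp distorts.
The regularised slot matches TKD closely at the default lambda and
approaches the true amplitude as lambda decreases.

## Source decomposition

Two observables constrain two unknowns per voxel: the net
susceptibility `chi = PCS + DCS` (opposite-sign sources cancel in
field) and the reversible dephasing rate `R2' = kappa (PCS + |DCS|)`
(they add in dephasing). `R2'` is R2* minus a non-susceptibility
baseline, from a per-tissue table in simulation or from the
contralateral normal-appearing white-matter median in application mode,
clipped at zero. The estimator is the constrained least squares

    min (pcs + dcs - chi)^2 + (pcs - dcs - R2'/kappa)^2
    s.t. pcs >= 0, dcs <= 0

with the closed-form interior solution `pcs = (chi + R2'/kappa)/2`,
`dcs = (chi - R2'/kappa)/2` and an explicit KKT projection when a sign
constraint binds. This is a deliberately simple two-pool static-
dephasing inversion with an implicit neutral pool (the baseline R2,
zero susceptibility); no claim of equivalence with more elaborate
multi-pool temporal-fitting separations is made. Because the phantom
uses the same forward relation, recovery on noiseless phantom data is
exact, which is what makes the decomposition unit-testable; robustness
is then checked separately under observation noise.

The magnitude-squared weighting of the log-linear R2* fit matters more
than it looks: log-domain noise scales as 1/S, and the unweighted fit
leaves enough R2* variance at SNR 50 to corrupt DCS (half of the R2'
error, divided by kappa) and flood the PDR map of edema with false
positives. The weighted fit is the standard heteroscedasticity-correct
choice.

## PDR and TIZ delineation

`PDR = PCS / max(|DCS|, epsilon)` with `epsilon = 1e-4 ppm`. The floor
only prevents division blow-up; floored voxels are retained because
genuinely huge PDR values are the signal, not an error. In the
contralateral hemisphere, subcortical nuclei are removed from the GM
mask (they are iron-rich and would inflate the reference), each
tissue's PDR values above their own 95th percentile are discarded
(outlier and segmentation-error guard; a pooled-trim variant is
available behind a flag, per-tissue is the default reading), and the
**maximum remaining GM PDR** becomes the threshold. Every edema voxel
outside the blood-exclusion mask with PDR *strictly above* the
threshold joins the TIZ. Two structural invariants follow directly: the
TIZ never leaves the edema-minus-exclusion region, and the PDR ranges
of the TIZ and of the retained contralateral GM cannot overlap.

## Blood exclusion

Perfusion and permeability catch complementary blood contamination:
intact-barrier hyperperfusion (nCBV above the 95th percentile of the
mirrored-tumor contralateral region) and leaky-barrier enhancement
(Ktrans above the 5th percentile of the enhancing-tissue
distribution, successful fits only). nCBV is the trapezoidal
AUC ratio of the leakage-corrected tissue curve to the arterial input
function (top-5 peak-ranked vessel voxels), normalised by the *median*
over contralateral normal-appearing white matter — the median rather
than an unspecified mean for robustness. The leakage correction fits
`dR2*(t) ~ K1 Rbar(t) - K2 int Rbar` against the non-enhancing
reference mean curve and adds the K2 term back.

## Statistics

The rank-sum test enumerates all rank assignments exactly for small
untied samples (min(n, m) <= 10) and otherwise uses the tie- and
continuity-corrected normal approximation. logPDR features use base-10
logs (the base only shifts features affinely, so correlations are
base-invariant; the base is recorded in the report), with the mode
estimated as the centre of the tallest Freedman-Diaconis histogram bin.
The sample-size calculation for a two-sided unequal-variance comparison
iterates `n = (t_{1-a/2,nu} + t_{power,nu})^2 (s1^2 + s2^2) / delta^2`
with Welch-Satterthwaite degrees of freedom evaluated at the current n
until a fixed point; the z-quantile shortcut is available behind a flag
but returns a smaller n, so the t-based convention is the default.

## Numerical choices and problem sizes

All spectral operators use periodic boundaries with the zero frequency
at index one and the main field along the third array axis. Erosions
are FFT ball convolutions. Conjugate-gradient solves run to a 1e-6
relative residual or the iteration cap (80 for the V-SHARP
deconvolution, 60 for the regularised inversion). The extended Tofts
fits use the 12-point multi-start grid over bounded L-BFGS-B, ties
resolved toward the smallest Ktrans; fits are only attempted inside
the tumor mask, where the exclusion rule needs them. The test suite
exercises the full pipeline at 64^3 (2 mm) and per-operation tests at
32^3 to 48^3 — sizes chosen so the whole suite runs comfortably on a
single CPU.

## Known limitations

* A piecewise-constant phantom at 2 mm has irreducible partial-volume
  error at compartment boundaries; whole-map recovery error is
  dominated by those edge voxels, and the sharp-interface condition is
  part of the phantom's design (no sub-voxel mixing is simulated).
* The TKD amplitude bias (about -18% on compact structures at clamp
  0.2) propagates into PDR nonlinearly; the GM-max threshold is
  computed from the same reconstruction, which partially compensates,
  but small, sharp infiltration pockets near the mask boundary remain
  the hardest targets.
* The decomposition is a two-pool static-dephasing model; frequency
  shifts from microstructure anisotropy, chemical exchange, or
  orientation effects are outside its vocabulary.
* Application to real data assumes co-registered inputs; registration,
  bias-field correction and segmentation are out of scope.
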