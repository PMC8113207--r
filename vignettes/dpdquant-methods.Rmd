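---
title: "Methods: quantitative cardiac bone-tracer SPECT/CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative cardiac bone-tracer SPECT/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dpdquant)
```

## The measurement model

Cardiac amyloid burden is quantified from a reconstructed SPECT/CT uptake
volume and a set of anatomical volumes of interest (VOIs). The chain is:

1. **Decay correction.** Voxel values are referred back to injection time:
   `c' = c · 2^(Δt/T½)`, with `Δt` the injection-to-acquisition interval in
   hours and `T½ = 6.0067` h for Tc-99m. The reference time is a
   convention; injection-time reference is the standard SUV convention and
   the one implemented. Since it is a global scalar, any other choice only
   rescales every SUV identically.
2. **SUV normalisation.** `SUV = c' / (A/W)` with injected activity `A`
   (MBq) and body weight `W` (kg). No camera/well-counter
   cross-calibration factor is applied: the scanner and dose calibrator
   are assumed uncalibrated against each other, so all SUVs are in
   *consistent but arbitrary* units. Every downstream quantity is either
   proportional to that unknown scale (DPD_mean, DPD_max, DPD_load) or
   invariant to it (V_42%, both sparing ratios) — the scale-equivariance
   tests pin this down.
3. **Isocontour segmentation.** Within an anatomical VOI, the segmented
   set is every voxel at or above 42 % of that VOI's maximum. Two choices
   deserve note:
   * *Per-VOI maximum*, not a global cardiac maximum. Under a global
     maximum, cooler regions (apex, RV free wall) could segment to the
     empty set; under per-VOI maxima every region has a well-defined,
     non-empty segmentation. Merged VOIs (`LV`, `VENTRICLES`) are
     thresholded as a whole, so a single merged maximum (in practice the
     septal one) governs them — which is why the merged LV maximum equals
     the hottest member maximum, and why a cold RV free wall can
     contribute almost nothing to the thresholded `VENTRICLES` volume.
   * *Inclusive comparison* (`≥`), so the maximum voxel is always
     retained and the output is never empty. An all-zero VOI makes the
     threshold degenerate; the full VOI is returned with a warning rather
     than an error, because a zero region is a data problem the caller
     should see, not a geometry failure.
4. **Metrics.** Over the thresholded set: mean SUV (DPD_mean), maximum
   SUV (DPD_max), volume in ml (V_42%), and the compound burden
   `DPD_load = DPD_mean · V_42%`. Computing the mean over the thresholded
   set (not the raw anatomical VOI) implies `DPD_mean ≥ 0.42 · DPD_max`
   structurally; the property tests enforce it. Decay correction and SUV
   are scalar multiplications and the threshold depends only on value
   ratios, so the order of the three steps is immaterial (also tested).
5. **Apical sparing.** From uptake: `apex / ((IVS + lateral)/2)` on
   regional DPD_mean, with no cut-off flag (no validated uptake cut-off
   exists). From strain: `apical / (basal + mid)` on signed averages —
   longitudinal strain is negative, so the ratio is positive — with
   relative sparing flagged at ratio strictly greater than 1.

## Region model

Base VOIs are `LV_LATERAL`, `IVS`, `APEX`, `RV_FREE_WALL`, `STERNUM`,
stored as one integer label per voxel (disjointness is structural). The
anterior/posterior segment splitting of the 16-segment echocardiographic
model is assumed to be already encoded in the input masks; the package
does not re-partition a generic segment mask, because that mapping is a
manual delineation step, not an algorithmic one.

`LV = LV_LATERAL ∪ IVS ∪ APEX` and `VENTRICLES = LV ∪ RV_FREE_WALL`.
Merging is a union of disjoint sets, so counts add.

**Sternum spill-over.** The sternum is typically much hotter than the RV
free wall, and resolution-driven spill contaminates RV voxels near it. The
exclusion rule removes RV voxels within `margin_mm` of the sternum mask,
implemented as an exact Euclidean dilation (offsets whose physical length
is at most the margin). The default margin is 10 mm — about one system
FWHM, the distance over which spill is non-negligible; the width of such a
border is a free parameter in practice and is exposed as
`sternum_margin_mm`. Margin 0 removes only overlapping voxels; the
exclusion is monotone in the margin and always a subset of the input.

## Reorientation

Clinical analysis reformats transaxial volumes into cardiac short-axis
orientation. Here the reformat angles are explicit inputs (three ordered
rotations about the grid axes, Z then X then Y, about the volume centre)
rather than an interactive step, making the operation deterministic.
Intensity volumes are resampled trilinearly, label masks by nearest
neighbour (labels are never blended or invented); out-of-field samples are
zero. Quantification is legal in either orientation: the acceptance suite
checks that jointly rotating a blurred phantom and its masks changes
DPD_mean by < 5 % and V_42% by < 10 % per region. That tolerance is about
interpolation and mask-boundary jitter, and it holds for volumes at
realistic smoothness; on a perfectly sharp (unblurred) piecewise-constant
volume, trilinear blending at wall edges can dilute thin-wall means by
more than 5 %, which is an artefact of testing on non-physical data, not
of the resampler.

## The phantom: what it emulates, and what it does not

`make_phantom()` builds a piecewise-constant concentration map: an
ellipsoidal LV shell (open at the base) partitioned into lateral, septal
and apical sectors by azimuth and long-axis position; a thinner RV
crescent fused at the septum; a hot sternum bar anterior to the RV free
wall, separated from the RV surface by a chest-wall gap of roughly
8–20 mm; a blood pool in the LV cavity; low background. The RV free-wall
label deliberately stays clear of the septal junction (an 8 mm margin
against the LV outer surface), as a delineator would: mask voxels at the
junction otherwise inherit septal spill and make the RV maximum — and
everything thresholded from it — unstable.

Defaults: 96³ voxels at 4.42 mm isotropic (the reconstructed voxel size is
a choice of this generator, typical for a 128×128 cardiac SPECT matrix,
not a measured fact); uptake ratios septum > lateral > apex > RV free
wall with a much hotter sternum; 12 mm FWHM Gaussian point-spread
function; Poisson noise at `count_scale = 50` expected counts per
concentration unit per voxel; metadata of 740 MBq injected 3 h before
acquisition, 74.6 kg body weight. One phantom builds in a few seconds.

The Gaussian PSF is the partial-volume surrogate: convolution depresses
the measured maximum of any structure thin relative to the PSF, more so
the thinner the wall — the behaviour the acceptance suite checks on an
18/12/8 mm wall-thickness ladder. The blur kernel is column-normalised, so
total counts are conserved exactly, including at the grid faces.

What the phantom does *not* emulate: anthropomorphic anatomy, attenuation
and scatter, projection-domain noise and reconstruction artefacts,
respiratory/cardiac motion, or inter-patient anatomical variation. A green
phantom test therefore establishes the correctness and stability of the
*measurement chain*, not clinical accuracy of the numbers on real
patients.

All randomness flows from the single integer `seed`; the generator draws
Poisson noise in one stream and restores the caller's RNG state, so
identical `(spec, seed)` pairs are bit-identical and callers' seeds are
undisturbed.

## The synthetic cohort

`make_cohort()` draws one latent severity `s ~ N(0,1)` per subject; every
variable with loading `λ` on severity is
`mean + sd · (λ·s + sqrt(1−λ²)·ε)`, so two variables with loadings `a` and
`b` have population correlation `a·b`. Anchor means and SDs for the uptake
metrics, regional strains and biomarkers reflect a severe type-A ATTR
cardiomyopathy cohort (e.g. ventricles DPD_load 10 144 ± 5 689 arbitrary
units, LV global longitudinal strain −17.0 ± 5.1 %, troponin T
28.8 ± 18.0 ng/l, log₁₀ NT-ProBNP 2.8 ± 0.6).

Design choices, fixed before the statistical tests were run:

* **Burden is the best correlate by construction.** `dpd_load` carries
  loading 0.95; `dpd_mean` and `dpd_max` carry 0.80. Burden compounds
  volume and intensity, both of which grow with disease severity, so it
  should track severity more tightly than either alone; the loadings
  encode that. With the strain loading set to hit
  `corr(dpd_load, strain) = 0.70`, the implied mean/max–strain
  correlations are ≈ 0.59.
* **Link targets.** Each regional burden–strain link targets r = 0.70;
  the ventricles burden–troponin and burden–log₁₀ NT-ProBNP links target
  0.558 and 0.356. Setting any loading to 1 gives the exact ±1 noiseless
  limit (used as a generator self-test).
* **Grades.** The visual grade comes from thresholding jittered severity
  (`s + N(0, 0.5²)`) at the marginal quantiles implied by expected grade
  fractions 3/48, 10/48, 35/48. The jitter decouples grade from burden
  enough to produce the characteristic grade 2/3 overlap while keeping
  grade 1–3 and 2–3 burden differences typically significant; jitter 0
  makes grades a deterministic function of severity.
* **Apical sparing prevalence.** The apical segment mean strain (−25.5 %)
  equals the basal (−10.5 %) plus mid (−15.0 %) means, so
  `P(ratio > 1) = 0.5` by symmetry regardless of the noise structure —
  the 50 % prevalence target is analytic, not tuned.
* **Physical floors.** Uptake metrics, troponin and strain magnitudes are
  floored at small physical values (e.g. burden ≥ 50, troponin ≥ 1,
  strain ≤ −0.1 %). The floors engage for a few percent of draws and
  perturb sample correlations by well under the testing tolerances.
* **Missingness.** Troponin, NT-ProBNP and RV strain are available for
  36, 40 and 34 of 48 subjects (drawn at random per seed; raw and log
  NT-ProBNP share the same missing subjects), and every pairwise analysis
  is complete-case with no imputation — so the report's `n_used` column
  varies by row exactly as the availability dictates.

The statistical layer itself is authored in the package (product-moment r
with the two-tailed t-test p; Kruskal–Wallis with mid-ranks and the
standard tie-correction, `p = 1` when all observations are identical) and
is verified against `stats::cor.test` / `stats::kruskal.test` as
independent oracles, including an exhaustive small-instance sweep. The
grade-vs-burden "1–3" and "2–3" comparisons are two-group Kruskal–Wallis
tests (equivalent to tie-corrected rank-sum tests); which exact pairwise
test clinical software uses varies, and this choice is documented rather
than hidden.

## Numerical and I/O choices

* **NIfTI-1 I/O.** Volumes and masks are single-file NIfTI-1; the
  built-in reader handles both endiannesses, gzip, the common scalar
  datatypes and `scl_slope`/`scl_inter`, and rejects non-3-D images and
  non-positive spacings. The writer emits float64 for volumes (lossless
  round-trip for R doubles) and int32 for masks. Negative reconstruction
  artefacts are clipped to 0 on ingestion with a logged count, because
  thresholding and SUV assume non-negative concentration. World
  orientation is informational: all quantification happens in voxel space
  of the (possibly reoriented) grid, and the volume and its masks are
  always transformed together.
* **Scale of the acceptance simulations.** The cohort recovery criterion
  uses 200 seeds (the lower end of its stated 200–500 range) to keep the
  default test run around ten seconds; the Monte-Carlo standard error of
  the mean link correlation at 200 seeds is ≈ 0.005, far inside the
  ±0.05 band. Phantom-based criteria run at 48³–64³ rather than the 96³
  default for the same reason; the geometry is identical (the structures
  fit well inside both grids), so the measured invariances are unchanged.

## Known limitations

* The phantom's geometry is stylised; absolute volumes (e.g. V_42% in ml)
  are internally consistent but not anthropomorphic.
* No partial-volume *correction* is implemented or attempted — the
  package measures the PVE-modulated uptake, as clinical quantification
  does, and the phantom exists partly to show how large that modulation
  is.
* SUVs are relative: comparisons across scanners or against
  cross-calibrated SUV literature values are out of scope.
* The synthetic cohort is a single-factor linear world; real cohorts have
  heavier tails, nonlinear biomarker dynamics and structured missingness.
  Green statistical tests establish that the analysis recovers the
  structure the generator put in, at the stated sample size — nothing
  more.
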