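# dpdquant

Quantitative cardiac bone-tracer SPECT/CT analysis for transthyretin
amyloidosis (ATTR).

Bone-avid tracers such as ^99m^Tc-DPD accumulate in type-A ATTR cardiac
amyloid, and the amount and distribution of myocardial uptake carries
information about disease severity that the visual Perugini grade does not
resolve. `dpdquant` implements the measurement chain that turns a
reconstructed SPECT/CT volume plus manually delineated volumes of interest
(VOIs) into quantitative burden scores, and the statistical layer that
relates those scores to echocardiographic strain and circulating
biomarkers. Intended users are nuclear-medicine physicists and imaging
researchers who have uptake volumes and label masks and want reproducible,
scriptable quantification.

## The measurements

For a VOI *V* on an uptake volume, with injected activity *A* (MBq), body
weight *W* (kg), injection-to-acquisition interval *Δt* (h) and isotope
half-life *T½* (6.0067 h for Tc-99m):

* **SUV**: each voxel value *c* becomes
  `SUV = c · 2^(Δt/T½) / (A/W)` — decay-corrected to injection time,
  normalised by injected dose per kilogram. No camera/well-counter
  cross-calibration is applied, so SUVs are in consistent but arbitrary
  units.
* **42 % isocontour**: the segmented set is
  `V₄₂ = { v ∈ V : c(v) ≥ 0.42 · max_V c }`, with the maximum taken over
  that VOI (merged VOIs are thresholded as a whole, under a single merged
  maximum).
* **DPD_mean, DPD_max**: mean and maximum SUV over `V₄₂`;
  **V_42%** its volume in ml; and the compound amyloid burden
  **DPD_load = DPD_mean · V_42%**.
* **Apical sparing**: from uptake,
  `apex / ((IVS + lateral)/2)` on regional DPD_mean; from strain,
  `apical / (basal + mid)` on signed average longitudinal strains, a
  subject showing relative sparing when the ratio exceeds 1.
* **Cohort statistics**: Pearson correlations with two-tailed t-test
  p-values (complete-case per pair), base-10 log transform for NT-ProBNP,
  and tie-corrected Kruskal–Wallis tests of burden across Perugini grades.

The standard VOIs are `LV_LATERAL`, `IVS`, `APEX`, `RV_FREE_WALL` (cleaned
of sternum spill-over by excluding voxels within 10 mm of the sternum
mask), and the merged `LV` (lateral + septum + apex) and `VENTRICLES`
(LV + RV free wall).

Because no public image data exist for this setting, the package ships a
digital cardiac phantom (`make_phantom()`) with ground-truth masks, a
Gaussian point-spread function standing in for partial-volume loss, and
Poisson counting noise — plus a synthetic 48-subject cohort generator
(`make_cohort()`) whose burden/strain/biomarker links are tuned to the
correlation magnitudes reported for real ATTRv cohorts.

## Worked example

```r
library(dpdquant)

ph <- make_phantom(phantom_spec(seed = 1))   # 96^3, 4.42 mm, 12 mm PSF, noise
metrics <- quantify_regions(ph$volume, ph$masks, ph$meta)
print(metrics, digits = 4)
#>         region dpd_mean dpd_max v42_ml dpd_load n_voxels_anatomical n_voxels_thresholded
#> 1   LV_LATERAL    4.103   5.575  54.40   223.20                 630                  630
#> 2          IVS    5.119   6.681  51.72   264.76                 600                  599
#> 3         APEX    3.610   4.703  12.61    45.51                 146                  146
#> 4 RV_FREE_WALL    1.870   2.756  26.60    49.73                 312                  308
#> 5           LV    4.546   6.681 115.45   524.88                1376                 1337
#> 6   VENTRICLES    4.546   6.681 115.45   524.88                1688                 1337
```

Read the row for `IVS`: mean SUV 5.12 (arbitrary units) over a 51.7 ml
thresholded septal volume gives a burden `DPD_load` of 265. The septum is
the hottest wall, the apex the coldest of the left-ventricular regions —
the uptake counterpart of apical sparing:

```r
apical_sparing_dpd(3.610, 5.119, 4.103)$ratio
#> 0.7828
```

A synthetic cohort and its correlation report:

```r
co <- make_cohort(cohort_spec(seed = 1))
rep <- build_correlation_report(co)
rep[rep$metric == "dpd_load" & rep$pair == "strain_LV", ]
#>     metric      pair region     r        p n_used
#>   dpd_load strain_LV     LV 0.705 2.19e-08     48
sparing_prevalence(co)
#> 0.4375
```

Here LV burden correlates with LV global longitudinal strain at r = 0.71
across 48 subjects, and 44 % of this particular cohort shows relative
apical sparing (the generator's long-run target is 50 %).

A command-line wrapper lives at `inst/cli/dpdquant.R`
(`quantify` / `phantom` / `cohort` subcommands).

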