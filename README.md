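# ablashape

Simulation and repeatability analysis of configurable thermal ablation
shapes.

Single-probe microwave ablation normally creates ellipsoidal coagulation
volumes. Retracting the probe along its axis while modulating power over
time and distance shapes the volume instead: an *ablation profile* — a
program of `(power, duration, distance)` intervals — can produce
elongated, hourglass, teardrop or pear-shaped ablations tailored to
irregular tumors. The scientific question this package addresses in
silico is whether such configurable shapes are as **repeatable** as the
standard static ones, judged the way a phantom study judges it: replicate
samples, cross-section photographs, colour segmentation, widths at 5 mm
steps, and a noninferiority test on a robust variability statistic.

The package is aimed at researchers designing or analysing ablation-shape
experiments in thermochromic tissue-mimicking phantoms, and at anyone who
needs a fully seeded synthetic benchmark for the measurement chain.

## What it implements

* **Profiles** — definition, validation, delivered energy
  (`total_energy`), and kinematic discretization of slow intervals into
  2 mm / 2 s steps plus dwells whose mean speed equals the commanded
  speed (`discretize`, `probe_position`). The ten study profiles ship as
  YAML fixtures (`study_profiles()`).
* **Heat simulation** — explicit finite-volume solver for
  `dT/dt = alpha lap(T) + q/(rho c)` in axisymmetric cylindrical
  coordinates, moving Gaussian source at the probe feed zone,
  coolant-limited shaft sink, fixed bath boundary, and the running
  per-cell *maximum* temperature (the thermochromic phantom records its
  maximum irreversibly), thresholded at 60 degC into an ablation mask.
* **Synthetic data** — cohorts of photograph-like cross-sections with
  per-sample generator-output draw (85–90 % of planned power),
  diffusivity jitter, coagulation-threshold jitter, a 1.5 mm colour
  gradient at the boundary, seeded noise and optional contour artifacts.
* **Segmentation** — weighted-HSV nearest-median classification with the
  decision boundary at the colour midpoint, largest 4-connected
  component, hole filling.
* **Morphometry** — widths at 5 mm measurement points, head/tail lengths
  beyond the trajectory, revolved volume and Wadell sphericity.
* **Statistics** — the repeatability metric (median absolute pairwise
  width difference per point, an Sn-type scale statistic), Mann–Whitney
  noninferiority with a 1 mm margin (Hodges–Lehmann effect, one-sided
  95 % bound), speed regression, and the simulation-based sample-size
  search.
* **Pipeline** — `run_experiment()` chains everything for all profiles,
  deterministically per seed, and writes CSV/JSON reports.

## Worked example

Simulate the teardrop profile, measure its shape, then generate and
measure a replicate cohort:

```r
library(ablashape)

tear <- study_profiles()[["TEAR-60W-600s"]]
tear
#> <ablation_profile> TEAR-60W-600s [TEAR]
#>   60 W  360 s  0 mm
#>   60 W  210 s  30 mm
#>   60 W  30 s  15 mm
#>   total: 600 s, 45 mm, 36.000 kJ

field <- simulate_ablation(discretize(tear),
                           function(t) profile_power(tear, t))
cross <- mask_image(field)
zs <- measurement_points(cross$meta$trajectory_length)
data.frame(z_mm = zs,
           width_mm = sapply(zs, function(z) width_at(cross$mask, cross$meta, z)))
#>    z_mm width_mm
#> 1     0       31
#> 2     5       30
#> 3    10       28
#> 4    15       24
#> 5    20       21
#> 6    25       19
#> 7    30       17
#> 8    35       13
#> 9    40       10
#> 10   45        7
head_tail(cross$mask, cross$meta, cross$meta$trajectory_length)
#>  head  tail
#>  0.00 15.25
```

The shape tapers from 31 mm at the static start to a 7 mm tip, ablation
extends 15 mm beyond the trajectory start (the tail) and not at all past
the moving end (the head) — the teardrop geometry this profile is
designed to produce.

```r
cohort <- generate_cohort(cohort_spec(tear, n = 6, seed = 42))
measured <- lapply(cohort, function(img)
  measure_sample(segment_image(img), img$meta, img$sample_id, "TEAR"))
summarize_cohort(measured)
#>    z_mm median_mm iqr_mm n
#> 1     0      30.5   1.75 6
#> 2     5      29.5   1.75 6
#> 3    10      27.0   1.50 6
#> ...
cohort_repeatability(measured, tear)$repeatability_mm
#>  [1] 1 1 1 1 1 1 1 1 0 6
```

Replicate widths spread by roughly 1–2 mm (IQR) per point and the
per-point repeatability is mostly 1 mm — except at the marginal tip,
where the width flickers between 0 and several mm across replicates.

A full study (10 profiles x 6 samples, segmentation never touching the
ground truth) runs in about a minute:

```r
report <- run_experiment(experiment_config(n = 6, seed = 7))
report
#> <study_report> 10 profiles, 60 samples, 47 repeatability points
#>   median repeatability (configurable): 1.00 mm
#>   median repeatability (standard): 1.00 mm
#> Mann-Whitney noninferiority (margin 1.00 mm, alpha 0.05)
#>   n = 41 (configurable) vs 6 (standard)
#>   p = 0.000173, delta = 0.00 mm, one-sided 95% CI <= 0.00 mm
#>   -> noninferior
```

## Notes

The thermal model is a calibrated conduction surrogate (Gaussian source,
no SAR antenna model, no perfusion); absolute dimensions are calibrated
to the 20–30 mm width range of the 60 W standard profiles, not predicted
from first principles. See the methods vignette
(`vignettes/configurable-ablation.Rmd`) for the model, parameter
rationale, generator realism and limitations.
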