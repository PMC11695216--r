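---
title: "Simulating configurable thermal ablation shapes and their repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating configurable thermal ablation shapes and their repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ablashape)
```

## The problem

Single-probe microwave ablation ordinarily produces ellipsoidal coagulation
volumes, which fit small spherical tumors but not elongated, waisted or
otherwise irregular targets. Retracting the probe along its axis while
modulating power over time and distance can *shape* the ablation volume:
an ablation profile is a program of `(power, duration, distance)` intervals,
and distinct programs produce elongated, hourglass, teardrop or pear-shaped
volumes. The empirical question is whether such configurable shapes are as
repeatable as the standard static ones.

`ablashape` is an in-silico replica of that experimental programme. It
covers the whole chain: profile definition and kinematic discretization, a
heat-conduction simulation of the tissue-mimicking phantom, rendering of
photograph-like cross-sections, colour-based segmentation, contour
morphometry, and the repeatability statistics. Every stage is seeded, so a
whole study is reproducible from one integer.

## Ablation profiles and probe kinematics

A profile is an ordered list of intervals; `total_energy()` accounts the
delivered energy (power x time). The bundled `study_profiles()` comprise
six standard static programs (OVAL, 60/100 W for 120/240/360 s) and four
configurable 600 s, 60 W programs (LONG, HOUR, TEAR, PEAR).

Robots cannot track continuous speeds below about 1 mm/s, so `discretize()`
converts slow moving intervals into alternating 2 mm / 2 s retraction steps
and waiting periods whose *mean* speed equals the commanded speed. Two
choices the program text leaves open are made explicit here: within a
segment the probe moves first and dwells second, and a non-divisible
remainder becomes a shorter final step with proportionally scaled times.
Both conserve total time and distance exactly, which the test suite asserts
to floating-point accuracy. Power is held constant across dwells
(continuous delivery), since generators are not switched during a program.

## The thermal model

The phantom is a water-rich polyacrylamide gel in a D54 x H90 mm container
tempered in a 37 degC bath, with a thermochromic ink that turns magenta
irreversibly above about 60 degC. The simulator solves the isotropic heat
conduction equation

$$ \frac{\partial T}{\partial t} \;=\; \alpha \nabla^2 T + \frac{q}{\rho c} $$

in axisymmetric cylindrical coordinates with an explicit finite-volume
scheme (cell-centred, fluxes cancel pairwise, so interior energy is
conserved exactly). The outer cell ring is clamped to the bath temperature.
The time step is set to 0.9 of the explicit stability limit
$1/(2\alpha(1/dr^2+1/dz^2))$ unless the user supplies one, which is then
validated. Because the ink records the *maximum* temperature, the
simulator tracks a running per-cell maximum; thresholding it at 60 degC
gives the ablation mask.

The probe is modelled as an isotropic Gaussian volumetric source (spread
`source_sigma`, default 3 mm) centred at the feed zone, 18 mm from the
tip. Key parameter choices, each exposed in `thermal_params()`:

* `diffusivity` 0.143 mm^2/s and `volumetric_heat_capacity`
  0.00418 J/(mm^3 K) — water-like values appropriate for a
  polyacrylamide gel.
* `efficiency` 0.875 — generator output as a fraction of the planned
  power; recorded outputs run at 85–90 % of the setting, and the cohort
  generator draws each sample's value uniformly from that band.
* `absorbed_fraction` 0.3 — the fraction of generator output that couples
  into the gel as heat. Reflection losses and heat carried away by the
  probe coolant dissipate the rest. This is the main calibration knob:
  with the full output deposited, 36 kJ would drive the entire 206 cm^3
  container past the 60 degC threshold (the container only needs ~20 kJ),
  which no physical sample shows. The default was calibrated once so the
  60 W standard profiles produce maximal widths of 20–30 mm;
  `calibrate_absorption()` re-fits it for other devices or media.
* `cooling_sink` 0.5 W/mm with `coolant_temp` 5 degC and a 2 mm
  `shaft_standoff` — the water-cooled shaft above the emitting section
  removes heat. Extraction is capped so the gel never cools below the
  coolant temperature, which keeps the explicit scheme stable and is
  physically the right saturation. Shaft cooling is what makes the
  proximal ("head") extent of continuously moving profiles nearly
  vanish while static dwells still grow a prominent head, and it is the
  mechanism behind the proximal indents seen on real samples; disabling
  it (`cooling_sink = 0`) produces heads of 6–8 mm on the elongated
  profile, which real samples do not show.

With these defaults (frozen once, before the acceptance checks were
written) the simulated shapes land close to the physical medians: LONG
plateaus at 27 mm, HOUR shows 28/10/26 mm lobes and waist, TEAR tapers
from 31 mm to a 7 mm tip, and PEAR grows from an 11 mm tip to 30 mm near
its slow end.

### Coordinate convention

The trajectory coordinate is zero at the *initial feed-zone position* (the
ablation profile starting point — where ablation actually begins) and
increases in the retraction direction. Head and tail are measured along
the probe axis line: tail = extent beyond the trajectory start (distal),
head = extent beyond the final retracted position (proximal). Placing the
origin at the probe *tip* instead would put the whole ablation 18 mm
"ahead" of the trajectory and make a zero tail a geometric necessity,
contradicting what cut samples show; the tip offset therefore only places
the source, never the measurements.

## The synthetic-data generator

`generate_cohort()` emulates a batch of physical samples. Per sample it
draws:

* generator output uniformly in 0.85–0.90 of the planned power,
* a relative diffusivity jitter (sd 3 %) standing in for gel
  inhomogeneity,
* a coagulation-threshold jitter (sd 2 degC): thermochromic inks switch
  over a tolerance band of a couple of degrees, not at a sharp
  temperature.

The threshold jitter is the dominant spread source: widths respond only
logarithmically to power, so the 85–90 % band alone moves contours by
~0.3 mm, while 2 degC at the ~2 degC/mm contour gradients shifts them by
the ~1 mm order that replicate samples actually show (per-point IQRs of
0–3 mm). Each sample's seed derives deterministically from the cohort
seed.

Rendering maps the signed distance to the mask boundary onto a linear
magenta/off-white blend over a 1.5 mm `gradient_width` (the middle of the
1–2 mm boundary-uncertainty band), blending in HSV along the shortest hue
arc so the gradient midline is exactly the colour midpoint, then adds
seeded per-channel noise. The exact phantom colours are unpublished, so
the defaults (magenta at hue 300 deg, warm off-white) are configuration
validated only by round-trip segmentation. `perturb_contour()` can add
the two artifact families seen on real cuts — lateral extrusions and
proximal indents — for robustness studies.

What the generator does *not* emulate: cutting-plane misalignment, lens
and lighting effects, spatially correlated gel inhomogeneity, and any
robot positioning error. Passing tests therefore show that the analysis
chain is correct and self-consistent under realistic colour, noise and
variability conditions — not that the physical system behaves identically.

## Segmentation

The colour-based two-class approach: pixels are provisionally labelled by
the nearest prior colour, per-class channel medians become the
image-specific model (one refinement pass, as a per-image median estimate
admits), and each pixel is classified by weighted Euclidean distance in
HSV — equivalently, thresholding at the colour midway between the two
medians, so the recovered boundary sits in the middle of the colour
gradient. Hue is treated circularly. The weights default to (1, 1, 0.5),
down-weighting value for lighting robustness; the weighting is
configuration because no canonical values exist. Exact distance ties go
to background — conservative under-segmentation of the ablated area.
Post-processing keeps the largest 4-connected component and fills interior
holes. On default-noise renders the round trip achieves Dice >= 0.98
against ground truth.

## Morphometry

Widths are measured every 5 mm along the trajectory (points at multiples
of 5 mm not exceeding the trajectory length; a static profile has the
single point 0), as the extent of the foreground run crossing the probe
axis. Volumes come from revolving the width profile
($V=\int \pi (w/2)^2\,dz$, trapezoid rule at 0.5 mm), surfaces from the
lateral surface of revolution plus end discs, and the sphericity index is
Wadell's $\psi=\pi^{1/3}(6V)^{2/3}/A$ (the index itself is never defined
in the experimental literature we mirror, so the standard definition is
used).

## Statistics

Repeatability at a measurement point is the median of the absolute
pairwise width differences across replicate samples — an Sn-type robust
scale statistic: translation invariant, scale equivariant, tolerant of
asymmetry and outliers. Noninferiority of the configurable group against
the standard group uses the location-shift Mann–Whitney construction:
U test of `conf - margin` vs `std`, one-sided, margin 1.0 mm, alpha 0.05,
exact null distribution for tie-free groups of at most 12, normal
approximation with tie correction otherwise. The effect estimate is the
Hodges–Lehmann median difference with a one-sided 95 % bound by test
inversion. Measurement points are treated as independent observations,
mirroring the experimental analysis; with heavily tied, quantized
repeatability values the Hodges–Lehmann interval can degenerate, in which
case the bound collapses to the point estimate.

`sample_size_search()` reproduces the simulation-based power analysis:
normal widths with pilot standard deviations (0.5 mm standard, 1.1 mm
configurable), a 0.5 standard:configurable generation ratio, and the
smallest sizes whose Monte-Carlo rejection probability reaches the target
(default $1-1/\text{reps}$, the finite-sample surrogate for "always
significant"). Common random numbers across candidate sizes keep the
power estimate monotone in the group size for a fixed seed. The printed
experimental pair (25/125) is inconsistent with the stated 0.5 ratio, so
it is not a reproduction target; the procedure is.

## Problem sizes and numerical choices

The default grid is 0.5 mm in both directions over the 27 x 90 mm
half-plane (54 x 180 cells; automatic time step ~0.35 s), which resolves
the 3 mm source and keeps a 600 s program near one second of computation;
renders default to 0.25 mm/px. The solver was verified against the
instantaneous point-source solution
$T = E/(\rho c\,(4\pi\alpha t)^{3/2})\,e^{-r^2/4\alpha t}$ on a 0.25 mm
grid (maximal error under 5 % of the peak). The full study configuration
is 10 profiles x 6 samples, which completes in a couple of minutes and is
bit-reproducible per seed.

## Known limitations

* The heat source is a calibrated Gaussian, not an electromagnetic (SAR)
  antenna model; absolute widths are calibrated, not predicted.
* No perfusion, vaporization or coagulation enthalpy — appropriate for
  this phantom, wrong for living tissue.
* The generator's variability is contour-gradient-driven; it reproduces
  the magnitude of replicate spread but not every empirical covariate
  relationship (e.g. the sign of the speed-vs-repeatability regression
  slope observed physically is not guaranteed here).
* Simulated repeatability at marginal shape tips (where a width flickers
  between zero and a few mm across replicates) can exceed the physical
  3 mm maximum; those points are honest outputs of the model, not
  measurement artifacts.
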