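---
title: "Dive classification, space use and habitat suitability modelling with divehab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dive classification, space use and habitat suitability modelling with divehab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divehab)
```

# The analysis problem

Plunge-diving seabirds such as gannets switch foraging tactics with prey
type: prolonged, deep, U-shaped dives with a distinct bottom phase are
associated with pursuit of demersal or spawning forage fish (capelin in the
Northwest Atlantic), while brief, shallow, V-shaped plunges target
surface-schooling pelagic fish (mackerel, saury, herring). Given GPS fixes
(nominally every 15 min) and 1-Hz depth traces from bird-borne
GPS/time-depth-recorder loggers, `divehab` turns the raw records into

1. a table of classified dive events with foraging locations,
2. dive-shape phenology and a year-by-shape contingency analysis,
3. kernel utilization distributions (UDs) of dive locations, and
4. per-dive-type habitat suitability maps from presence/pseudo-absence
   binomial additive models driven by bathymetry, seafloor slope, daily sea
   surface temperature (SST) and position.

Because raw tracking data of this kind are rarely public, the package also
ships a central-place foraging simulator with known habitat truth; every
stage of the pipeline is validated against that truth in the test suite.

# Dive processing

## Detection and metrics

A dive is a maximal run of depth samples above a surface threshold
(default 0.5 m, a guard against pressure-sensor noise; samples arrive at
1 Hz only while the bird is submerged). Per dive we compute:

* **maximum depth** (m) — the largest sample;
* **duration** (s) — last minus first timestamp plus one sampling
  interval, so a single-sample dive lasts 1 s rather than 0 s;
* **bottom time** (s) — total time at depth at or beyond 80% of the
  dive's maximum depth.

The 80% bottom-phase convention deserves a note: field studies usually
delegate this quantity to a dive-processing package without stating a
definition. We adopt depth ≥ `bottom_frac` × max-depth (default 0.8)
because it is a common operational choice, it is monotone in the sense the
classifier needs (a true bottom phase at depth always registers), and it is
exposed as a parameter for sensitivity analysis.

Dives shallower than 1 m are then removed — such excursions are plausibly
bathing rather than foraging — and the filter is applied *after*
detection, on maximum depth, keeping detection and biological filtering
separate.

## U/V classification

The classification rule is

> U if and only if bottom time ≥ 3 s, **or** (duration > 10 s **and**
> maximum depth > 8 m); otherwise V.

The field literature phrases the two classes with overlapping clause pairs
("bottom time ≥ 3 s, and/or duration > 10 s and depth > 8 m" for U versus
the mirrored inequalities for V). Those clause sets are not logical
complements — a dive with bottom time 2 s, duration 10 s, depth 9 m
satisfies neither description — so a precedence has to be chosen. We make V
the exact complement of U under the rule above, which matches the
characterization of V dives as rapid and shallow; a `strict_and` variant
(U requires all three conditions) is available through
`classify_dive(rule = "strict_and")`.

## Foraging locations and breeding phase

A dive's foraging location is the GPS fix of the same bird recorded within
30 min before (or at) the dive start; if several qualify, the latest is the
best spatial proxy for the dive site and is used. We take one location per
dive rather than admitting multiple presences per dive, so downstream
sample sizes count dives, not fixes. Dives with no qualifying fix keep `NA`
coordinates and are excluded from presence generation.

V-shaped dives are split into early and late chick-rearing at a per-year
cut-off date. Two modes exist: `fixed_date` (supply known dates) and
`auto`, which scans every candidate split day and returns the day
maximizing the difference between the mean daily U-dive proportion before
and after the split, ties broken earliest. The exhaustive scan is cheap
(seasons are at most a few hundred days). One caveat we document rather
than hide: for a perfectly linear decline in daily U-proportion the
two-mean contrast is analytically constant in the split position, so the
earliest split wins by the tie rule; the `auto` mode is intended for
phenologies with a genuine drop, and a constant profile triggers a warning
and a midpoint return. U dives also receive a phase label; it is ignored
when tabulating (U is a single column in the contingency table), but
carrying it keeps bookkeeping uniform.

# Contingency analysis

`chi_square_independence()` implements the Pearson test directly: expected
counts from the product of margins, residuals `(O - E) / sqrt(E)`, the
statistic as the sum of squared residuals (no continuity correction, as is
standard for df > 1), and the upper-tail p-value from the chi-square
distribution. Expected counts are kept at full precision and rounded only
for display. A degenerate margin (an expected cell of zero) is an error,
not an `NaN`. The builder `build_table()` tabulates years against
`U`, `V-early`, `V-late`.

# Space use

UDs use an isotropic bivariate Gaussian kernel on a kilometre grid. Points
are first projected to an azimuthal-equidistant plane centred on the
colony: the projection preserves distances from the central place, which is
the geometry that matters for a central-place forager, and keeps the kernel
isotropic in km. The grid pads the point extent by 3 bandwidths and the
surface is renormalized to unit mass, so truncation at the grid edge never
biases isopleths.

The smoothing bandwidth follows the rule `h = 2 × ln(mean foraging range in
km)`: the mean over trips of the maximum great-circle distance from the
colony, logged and doubled. The log base is not universal in the tools this
rule originates from; we use the natural log, which maps a plausible
~55 km mean range to h = 8 km, and expose the base and factor as arguments.
Ranges of 1 km or less are rejected (non-positive log).

The p% isopleth is the smallest set of highest-density cells whose mass
reaches p, computed by sorting cell masses — so the 50% region is contained
in the 95% region by construction. One property worth knowing when
validating UDs against held-out data: the 50% isopleth of a kernel
*estimate* is the 50% highest-density region of the smoothed distribution,
which for points with spread σ and bandwidth h covers roughly
`1 − exp(−ln 2 · (σ² + h²)/σ²)` of new draws from the same distribution —
about 55% at σ = 20 km, h = 8 km, not 50%. Smoothing widens the region;
calibration statements about isopleths should account for that bias, and
our test suite checks calibration at a bandwidth small relative to the
point spread (h = 4 km), where the bias is ~1 point.

# Habitat suitability modelling

## Domain and pseudo-absences

The analysis domain is the set of sea cells within `1.1 ×` the maximum
colony-to-dive great-circle distance. Published domains of this kind are
often drawn by hand (padding the observed extent, clipping to a shelf break
or a latitude); the radius rule captures the algorithmic content — pad the
observed foraging extent by 10% — and a user-supplied mask can replace it
where a bespoke domain exists.

For each presence (a dive's foraging location), three pseudo-absences are
drawn uniformly over domain sea cells (uniform within the cell), each with
a uniform random date within that year's tracking period. The 3:1 ratio is
standard for presence/background habitat models of this kind and is exact
by construction, not in expectation. Sampling is reproducible from an
explicit seed.

## Covariates and concurvity

Each record gets bathymetry and slope from its containing cell, SST from
the layer nearest its date, and distance to the colony. Records on land or
no-data cells are dropped with a reported count. Before fitting, candidate
smooth terms are screened for pairwise concurvity — the nonlinear analogue
of collinearity — using the fitted additive model's basis projections; a
term whose worst pairwise concurvity exceeds 0.9 is dropped. Distance to
colony is screened first because it is a deterministic function of
longitude and latitude and is, in practice, always flagged against the
lon/lat surface on a colony-centred domain; the screen exists so this is
measured rather than assumed.

## Model, selection, prediction

`hsm_fit()` fits a binomial (logit) additive model: thin-plate regression
spline smooths (k = 10) for bathymetry, slope and SST, a two-dimensional
thin-plate smooth (k = 25) for longitude/latitude, and year as a
categorical fixed effect (individuals are deliberately not random effects:
the fitted model must predict into new data, and subject-level random
effects do not transfer). Smoothing parameters are chosen by the GCV/UBRE
criterion of `mgcv`. Basis sizes are defaults, not claims; both are
arguments.

Model selection is an all-subsets search over the smooth terms with year
always retained. Candidates are ranked by the small-sample Akaike
criterion

AICc = −2ℓ + 2k + 2k(k + 1)/(n − k − 1),

with k the *effective* degrees of freedom of the penalized fit (sum of
smooth edf plus parametric terms), and summarized by ΔAICc and Akaike
weights `w ∝ exp(−Δ/2)`. The selected model minimizes AICc over a set that
contains the global model, so its AICc never exceeds the global model's.

Daily prediction evaluates the inverse-logit linear predictor at every
domain cell centre with that day's SST layer (nearest date, no temporal
interpolation). Two numerical choices matter here. First, covariates
outside the training range are clamped to the range endpoints before
evaluation: penalized splines extrapolate polynomially and a single cold
offshore cell can otherwise produce an absurd probability; the number of
clamped values is reported. Second, for a single pooled map the year fixed
effect is set to the mean of the year effects on the link scale
(configurable to any single year); averaging on the link scale keeps the
operation inside the model's additive structure. Mean and error maps are
the per-cell arithmetic mean and population standard deviation over days,
with the SD forced to exact zero where all dailies agree.

# The simulator

`gen_environment()` builds a coastal shelf: land north of the colony's
coastline, depth increasing offshore with a cross-shelf ridge and smooth
low-frequency noise (so slope varies), and a daily SST stack with a
latitudinal gradient, linear seasonal warming and smooth daily noise —
giving the early/late SST contrast a real season has.
`gen_tracks_and_dives()` then simulates round trips: per trip, dive sites
are drawn independently over sea cells with probability proportional to
`exp(w · z)` where `z` are standardized bathymetry/slope/SST and `w` are
per-shape habitat weights (U prefers shallow, flat, cool cells; V is
broader, warmer, steeper). Sites are visited in greedy nearest-neighbour
order at 15 m/s; fixes are emitted every 15 min plus one at each site
arrival, so every dive has a fix within its 30-min association window by
construction. Depth traces carry Gaussian sensor noise (sd 0.1 m): U dives
descend to 10–22 m with a 5–12 s bottom phase; V dives spike to 1.3–7.5 m
for 5–7 s. These profiles sit away from the classifier thresholds
(bottom ≥ 5 s, duration ≤ 8 s), so label recovery through the full
detection chain is expected to be exact; sensitivity of the classifier at
its boundaries is tested separately with hand-built profiles.

The defaults — 8 birds, a ~2-month season, 15-min fixes, ~8 dives per
trip, a step drop in the daily U-dive proportion 45% of the way through
the season (0.7 to 0.05) — emulate a single-colony tracking study of a few
dozen birds. What the simulator does *not* emulate: energetics and
provisioning constraints, tag effects, tides and currents, spatially
autocorrelated movement beyond the trip structure, or observation gaps
(dropped fixes, truncated traces). Consequently, passing tests demonstrate
the pipeline's correctness and statistical calibration under clean
sampling, not robustness to the messiness of real deployments.

Calendar dates are handled as integer day-of-study internally and ISO-8601
at I/O boundaries. Every stochastic operation takes an explicit seed, and
the pipeline derives per-stage seeds from one master seed, so a fixed seed
reproduces a run exactly.

# Problem sizes and runtime

The test suite runs entirely on simulated data: unit fixtures use 2–4
birds over 10–45 days (hundreds to ~2200 dives); the goodness-of-fit check
of dive-site placement uses 10,000 dives; the end-to-end recovery run uses
~1500 presences with 3:1 pseudo-absences over a ~3100-cell domain; the
selection-consistency experiment uses 50 replicates of n = 3000; the
chi-square calibration uses 2000 multinomial replicates. These sizes were
chosen so that Monte-Carlo noise is small relative to every asserted
margin while a full run stays comfortable on a single CPU.

# Known limitations

* Raster I/O is plain-text ESRI ASCII grid, one file per layer; there is
  no GeoTIFF reader/writer, and no reprojection — all layers must share
  one lon/lat grid.
* The concurvity screen uses one estimator (basis-projection norms via
  `mgcv::concurvity`'s "estimate" measure); other definitions exist and
  can rank borderline terms differently.
* The auto cut-off detector assumes a step-like drop in U-dive proportion;
  gradual declines resolve to the earliest tie (documented above).
* Isopleth polygons are exported as unions of cell squares, not smoothed
  contours; the cell mask is the analysis object.
* The habitat model is a presence/background design: fitted probabilities
  are relative suitability indices, not absolute occurrence probabilities,
  and depend on the pseudo-absence ratio.
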