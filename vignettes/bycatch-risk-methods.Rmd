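---
title: "Modelling juvenile sea turtle bycatch from effort-abundance overlap"
author: "turtleRisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling juvenile sea turtle bycatch from effort-abundance overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turtleRisk)
```

## The model

Sea turtle bycatch in a fishery is treated as the product of three
quantities in each 1° × 1° coastal cell and year: the number of juvenile
turtles predicted to be present (`T_p`), the amount of gear-specific
fishing effort (`F`), and a gear's catchability (`q`). Where bycatch was
actually observed, a *minimum* bycatch rate can be computed directly:

    q = T_b / (T_p * F)

with `T_b` the observed count. The estimate is a minimum because observed
bycatch necessarily undercounts true bycatch; cells without observed
bycatch carry no information about `q` and are not considered. Rates for
a species-gear combination typically span orders of magnitude, so they
are pooled by **geometric mean**, bracketed by the geometric mean of the
rates below the pooled value (lower bound) and above it (upper bound).
Annual total bycatch is then extrapolated over the **risk index**
`R = T_p * F` summed across all cells:

    B_y = GM(q) * sum_bins R(bin, y)

and expressed as a percentage of the modelled juvenile population,
`P_y = 100 * sum_gears B_{g,y} / N_y`.

The package implements each stage behind an S4 container (`BinGrid`,
`HarmonizedEffort`, `AbundanceField`, `BycatchRates`, `RateSummary`,
`BycatchEstimate`) with accessors rather than slot access.

## Effort harmonization

Raw effort arrives in gear-specific units and spatial aggregations; the
`effort` functions map everything to per-bin exposure:

* **Shrimp trawl**: days trawled × typical trawl speed, using the
  published km/day constants (128.9 Gulf, 115.6 Atlantic) verbatim
  rather than recomputing from knots, so converted series match the
  published ones bit for bit (`knotsToKmPerDay()` keeps the derivation
  testable). Years where only an Atlantic-wide or Gulf-wide total exists
  are handled by `extendAtlanticShrimp()` (back-fill at ×0.225, the
  complement of the observed 77.5 % mean reduction) and
  `partitionGulfLatestYear()` (prior-year relative distribution).
  Atlantic totals are split by the published subregion weights, which
  sum to 0.999 and are deliberately not renormalized.
* **Bottom longline / gillnet**: set length × sets × soak time, with the
  soak assumed at 5 h = 0.2083 d for longlines and reported for gillnets.
* **Hook and line**: lines × hours/24.
* **Recreational**: angler trips × state mean trip duration (5.6 h Texas
  … 2.4 h North Carolina), in days.

Area-level effort is spread evenly across the area's coastline bins
(`rasterizeEffort()`; Texas effort divided by 4, a single-bin area
unchanged), conserving totals to machine precision. Bin membership is
configuration data, not code, so any geography — including the synthetic
one — can supply its own tables.

## Recruitment by passive drift

Juvenile abundance is built from hatchling production `H(region, cohort)`
dispersed passively through a surface velocity field. The advection
kernel is a fixed-step RK4 integrator (half-hour default) with
bilinear-in-space, linear-in-time velocity interpolation — the standard
tracer scheme. Particles leaving the grid are frozen and flagged
`exited`; particles stepping into a land cell are frozen at the last wet
position and flagged `beached` (no beaching/resuspension model). Released
particle count is conserved at every step.

The study design releases 350 particles/day over a 60-day emergence
window (21,000 per region-year). Positions are sampled at ages 0.5, 1.5,
2.5, 3.5 yr (`age × 365.25` days, nearest stored step — the day
convention is not otherwise constrained, so the astronomical year was
chosen); particles inside coastal bins are recruits and the per-bin
fraction `p` is recruits over releases. Abundance components are

    component(bin, y, region, a) = H(region, y - ceiling(a)) * p * s^a

with `s = 0.817` annual oceanic survival applied as the daily rate
compounded over the age (`dailySurvival(0.817)^365 = 0.817` exactly, so
the annual median is reproduced at integer ages). The cohort convention
`y - ceiling(a)` (a turtle aged 0.5 in year `y` hatched in `y - 1`) is a
design choice exposed through the `cohortOffset` argument, since either
rounding is defensible for mid-year ages. Species drift caps (2.5 yr for
Kemp's ridley, whose oceanic stage the drift window covers fully; 3.5 yr
for green) limit the ages that contribute. A missing cohort's hatchling
production is an error, never a silent zero.

## Numerical choices

* RK4 is exact for uniform flow and shows clean 4th-order convergence on
  solid-body rotation (error ratio ≈ 16 when the step halves); the
  half-hour step keeps one-period orbit-radius drift near 1e-11 relative.
* Analytic flows (uniform, solid rotation, double gyre) back the
  synthetic worlds because they admit closed-form reference trajectories;
  the double gyre uses a 2:1 domain so its discrete divergence vanishes
  on the 1° lattice. Gridded fields from other sources enter through the
  long-format CSV reader with the same (time, lat, lon, u, v) schema.
* Rates "equal to the GM" are excluded from both bound partitions; the
  tie is judged at 1e-12 relative because exponentiating the mean log
  perturbs exact ties by a few ulps.
* Annual geometric means exclude zero years rather than degenerating to
  zero; gears that never catch are reported categorically instead.
* Trend tests are two-sided Pearson correlations (`stats::cor.test`)
  with no multiplicity correction; the rate-trend check regresses
  `log(q)` on year, the scale consistent with geometric-mean pooling.
* Bins are half-open `[lat, lat+1) × [lon, lon+1)` with integer-floor
  ids, so boundary points are assigned unambiguously.

## The synthetic world and what it does (not) show

`makeSyntheticWorld()` defines a Gulf-like system: a 17 × 8 grid with a
16-bin coastline split into six areas (Texas spanning four bins and
Mississippi one, mirroring the real coastline's worked examples), four
nesting regions, a double-gyre flow, and three fisheries with constant
known catchabilities. Hatchling production (order 1e5 per region, 3 %/yr
growth) and effort follow linear trends with multiplicative lognormal
noise (sd 0.1 and 0.15 — effort is positive, so noise is lognormal by
design); the shrimp-trawl trend declines while gillnet and recreational
effort grow, echoing the contrast seen in the real fisheries. All
randomness fans out from one root seed through fixed child streams
(`childSeed()`), so components regenerate independently and bundles are
byte-identical across runs.

Observed bycatch is Poisson with mean `q_true * T_p * F`. The default
catchabilities place that mean at ≥ 50 in every cell, which makes the
generator an informative test bed: conditioning on observation is then
negligible and the pipeline must recover `q_true` within a few percent
(the acceptance checks require 10 %). At realistic sparsity the same
conditioning *inflates* rates — only lucky cells are observed — which is
why the estimator is a minimum-rate method; the test suite demonstrates
that inflation qualitatively at small means. The closed-form recruitment
fractions used by `genAbundance()` (exponential alongshore decay,
coastal mass declining with age) stand in for the drift simulation in
estimator tests; the advection path itself is exercised against analytic
flows and, end to end, at reduced particle counts. None of this emulates
observer coverage fractions, reporting behaviour, swimming, or real
shelf circulation — passing tests show the pipeline's arithmetic and
accounting are right, not that the ecological inputs are.

Problem sizes used throughout (10 study years, 16 coastal bins, a few
hundred bin-year rates per gear, drift demos at a handful of particles
per day) were chosen so the whole suite documents the method at desk
scale; the release-schedule defaults remain the full 350/day × 60 d
design and scale linearly if run.

## Reproducing published-scale numbers

The headline published rates and annual totals depend on the compiled
multi-decade effort, abundance and bycatch data, which are distributed
as a supplementary spreadsheet rather than shipped here. The package
reads that layout (sheet per gear; bin columns headed by four-digit
lat/lon codes such as `2897` = 28.5° N, 97.5° W) via
`readSupplementDir()` once the sheets are exported to CSV, after which
`summarizeRates()` / `extrapolateBycatch()` reproduce the published
procedure deterministically. Without that file, the verifiable surface
is the synthetic-recovery and identity suite above — which is exactly
what `scripts/acceptance.R` recomputes.

## Known limitations

* Passive drift only: no swimming, habitat selection, or density
  dependence; abundance shares the hatchling-production coverage gaps of
  its inputs (near-complete for Kemp's ridley, partial for green).
* The minimum-rate construction is biased low by unobserved bycatch and
  biased high by ignoring zero-catch locations; it is best read as a
  relative risk ranking across gears.
* Area-level matching (recreational records by state) divides summed
  counts by products of summed `T_p` and `F`; bin-level and area-level
  rates are therefore not numerically interchangeable, and each gear is
  extrapolated at the granularity its records were matched at.
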