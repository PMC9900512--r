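# turtleRisk

Spatial risk modelling of juvenile sea turtle bycatch in coastal
fisheries. The package is for quantitative ecologists and fisheries
scientists who need to rank bycatch risk across heterogeneous gears
(shrimp trawls, bottom longlines, gillnets, hook-and-line, recreational
angling) when observer coverage is sparse or absent.

## The method

Bycatch is modelled through the spatial overlap of fishing effort and
modelled turtle abundance on a 1° × 1° grid. Where bycatch was observed,
a minimum bycatch rate (catchability) is

```
q = T_b / (T_p · F)
```

with `T_b` the observed count, `T_p` the modelled juvenile abundance and
`F` the gear-specific effort in that bin-year. Rates are pooled per
species-gear by geometric mean, bracketed by the geometric means of the
rates below/above the pooled value, and extrapolated over the summed risk
indices `R = T_p · F` to annual totals `B_y = GM · Σ R(bin, y)` and
percent-of-population `P_y = 100 · Σ_g B_{g,y} / N_y`.

`T_p` comes from an age-structured passive-drift model: hatchling
production per nesting region, RK4 Lagrangian advection through a
gridded surface velocity field (half-hour steps, bilinear/linear
interpolation), classification of particles in coastal bins at ages 0.5,
1.5, 2.5, 3.5 yr, and annual oceanic survival of 0.817 compounded daily.
Effort harmonization implements the gear unit conversions (e.g. 1 trawl
day = 128.9 km in the Gulf, 115.6 km in the Atlantic; 5 h longline soak
= 0.2083 d; angler trips × state trip duration) and the spatial
partitioning/back-fill rules for incomplete series.

A synthetic-data generator (`makeSyntheticWorld()`) with analytic flow
fields and known catchabilities makes the entire pipeline verifiable by
parameter recovery; see the methods vignette
(`vignettes/bycatch-risk-methods.Rmd`).

## Worked example

```r
library(turtleRisk)

world <- makeSyntheticWorld(seed = 1)          # known q_true per gear
ab    <- genAbundance(world)                   # T_p per bin-year
eff   <- harmonizeEffort(genEffort(world), areaMembership(world@grid))
byc   <- genBycatch(ab, eff, world@catchability, seed = childSeed(1, 3))

rates <- computeRates(byc, ab, eff, by = "bin")
summ  <- summarizeRates(rates)
formatRateSummary(summ)
#>        species         gear                rate
#> 1        green      gillnet 1e-04 (1e-04-1e-04)
#> 2        green recreational 2e-06 (2e-06-2e-06)
#> 3        green shrimp_trawl 1e-06 (9e-07-1e-06)
#> 4 kemps_ridley      gillnet 2e-04 (2e-04-2e-04)
#> 5 kemps_ridley recreational 4e-06 (4e-06-4e-06)
#> 6 kemps_ridley shrimp_trawl 2e-06 (2e-06-2e-06)

est <- extrapolateBycatch(summ, riskIndices(ab, eff, by = "bin"))
annualSummary(est)
#>        species         gear n_years gm_annual
#> 1        green      gillnet      10  3299.786
#> 2        green recreational      10  3591.285
#> 3        green shrimp_trawl      10  2242.225
#> 4 kemps_ridley      gillnet      10  3326.335
#> 5 kemps_ridley recreational      10  3914.819
#> 6 kemps_ridley shrimp_trawl      10  2265.239
```

Each formatted rate is the geometric mean of all per-bin-year minimum
rates for that species-gear with its lower/upper bound bracket (a
singleton rate set renders `(--)`); the recovered geometric means sit
within ~1–2 % of the generating catchabilities at the default
(observation-rich) settings. `annualSummary()` gives the geometric mean
over years of the extrapolated annual totals. The same flow runs from a
YAML config and on-disk CSV bundles via `runSimulate()` /
`runEstimate()`, or from the shell through
`inst/scripts/bycatch_pipeline.R`.

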