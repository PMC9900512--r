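Package: turtleRisk
Title: Spatial Risk Modelling of Juvenile Sea Turtle Bycatch in Coastal Fisheries
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates gear-specific sea turtle bycatch rates and annual total
    bycatch from the spatial overlap between fishing effort and modelled
    juvenile turtle abundance. Harmonizes heterogeneous fishing-effort records
    (trawl, longline, gillnet, hook-and-line, recreational) into per-bin
    exposure units, predicts coastal recruitment of juvenile turtles by passive
    Lagrangian drift with age-structured oceanic survival, derives per-bin-year
    bycatch rates from sparse observed-bycatch records, summarizes them by
    geometric mean with lower/upper bound brackets, and extrapolates annual
    totals and percent-of-population risk over abundance-by-effort risk
    indices. Includes a synthetic-data generator with analytic flow fields and
    known catchabilities so the entire pipeline is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'velocity.R'
    'advection.R'
    'grid.R'
    'effort.R'
    'recruitment.R'
    'estimator.R'
    'observer.R'
    'synthetic.R'
    'pipeline.R'
    'supplement.R'
    'turtleRisk-package.R'
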