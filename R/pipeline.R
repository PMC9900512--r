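#' @include synthetic.R estimator.R effort.R recruitment.R observer.R
NULL

#' Default pipeline configuration
#'
#' A plain list describing one end-to-end run: where inputs live (or the
#' synthetic-world spec to generate them), which species/gears/years to
#' process, how abundance is obtained, and the root seed. Round-trips
#' through YAML unchanged.
#'
#' @param seed root seed for all generated randomness.
#' @param years study years.
#' @param outdir directory for generated inputs and results.
#' @param abundanceMethod "direct" (closed-form synthetic recruitment
#'   fractions) or "advection" (run the drift simulation over the world's
#'   flow field).
#' @param particlesPerDay,windowDays release schedule for the advection
#'   method (the full study design is 350/day over 60 d; smaller values
#'   keep demonstration runs light).
#' @param areaLevelGears gears whose bycatch records are aggregated by
#'   state/area rather than bin (default "recreational").
#' @return a named list (class "turtleRiskConfig").
#' @export
pipelineConfig <- function(seed = 1L, years = 1996:2005, outdir = tempdir(),
                           abundanceMethod = c("direct", "advection"),
                           particlesPerDay = 350, windowDays = 60,
                           areaLevelGears = "recreational") {
  cfg <- list(seed = as.integer(seed), years = as.integer(years),
              outdir = outdir,
              abundance_method = match.arg(abundanceMethod),
              particles_per_day = particlesPerDay,
              window_days = windowDays,
              area_level_gears = areaLevelGears)
  class(cfg) <- c("turtleRiskConfig", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a configuration list from \code{\link{pipelineConfig}}.
#' @return \code{readPipelineConfig} returns the configuration list.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed) || is.null(cfg$years))
    configError("config must define 'seed' and 'years'")
  cfg$seed <- as.integer(cfg$seed)
  cfg$years <- as.integer(cfg$years)
  if (length(cfg$years) == 0L) configError("config 'years' is empty")
  class(cfg) <- c("turtleRiskConfig", "list")
  cfg
}

#' Generate the synthetic input bundle on disk
#'
#' Builds the synthetic world from the config seed and writes every
#' pipeline input as CSV — raw per-gear effort, bin membership, hatchling
#' production, abundance components, observed bycatch — plus a
#' ground-truth manifest (true catchabilities, flow spec, survival) as
#' YAML. With \code{abundance_method = "advection"} the abundance grid is
#' produced by the drift simulation instead of the closed-form fractions,
#' and the velocity field is written too.
#'
#' @param cfg configuration from \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the world and the file paths written.
#' @export
runSimulate <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  world <- makeSyntheticWorld(seed = cfg$seed, years = cfg$years)
  paths <- list()
  raw <- genEffort(world)
  for (g in names(raw)) {
    p <- file.path(cfg$outdir, paste0("effort_", g, ".csv"))
    utils::write.csv(raw[[g]], p, row.names = FALSE)
    paths[[paste0("effort_", g)]] <- p
  }
  memb <- areaMembership(world@grid)
  utils::write.csv(memb, paths$membership <- file.path(cfg$outdir, "membership.csv"),
                   row.names = FALSE)
  utils::write.csv(world@hatchlings,
                   paths$hatchlings <- file.path(cfg$outdir, "hatchlings.csv"),
                   row.names = FALSE)

  abund <- if (identical(cfg$abundance_method, "advection"))
    simulateAbundanceByDrift(world, cfg) else genAbundance(world)
  utils::write.csv(abundanceComponents(abund),
                   paths$abundance <- file.path(cfg$outdir, "abundance.csv"),
                   row.names = FALSE)

  harm <- harmonizeEffort(raw, memb)
  byc <- genBycatch(abund, harm, world@catchability,
                    seed = childSeed(world@seed, 3L))
  utils::write.csv(byc, paths$bycatch <- file.path(cfg$outdir, "bycatch.csv"),
                   row.names = FALSE)

  manifest <- list(seed = world@seed,
                   years = as.integer(world@years),
                   survival_annual = world@survivalAnnual,
                   flow = world@flow,
                   q_true = as.list(stats::setNames(
                     world@catchability$q,
                     paste(world@catchability$species,
                           world@catchability$gear, sep = "."))),
                   species_caps = as.list(stats::setNames(
                     world@species$max_age, world@species$species)))
  yaml::write_yaml(manifest,
                   paths$manifest <- file.path(cfg$outdir, "manifest.yaml"))
  invisible(list(world = world, paths = paths))
}

## abundance via the drift simulation over the world's analytic flow
simulateAbundanceByDrift <- function(world, cfg) {
  caps <- stats::setNames(world@species$max_age, world@species$species)
  if (!is.null(cfg$species_caps)) # optional trim for light demo drifts
    caps[names(cfg$species_caps)] <- unlist(cfg$species_caps)
  maxAge <- max(caps)
  vf <- genWorldVelocity(world, days = ceiling(maxAge * DAYS_PER_YEAR) +
                           cfg$window_days + 2)
  land <- bins(world@grid)
  land <- land[land$bin_lat >= 29, c("bin_lat", "bin_lon")]
  sched <- makeReleaseSchedule(world@regions, cohort = 0L,
                               perDay = cfg$particles_per_day,
                               windowDays = cfg$window_days)
  traj <- advectParticles(vf, sched, duration = maxAge * DAYS_PER_YEAR,
                          stepHours = cfg$step_hours %||% 0.5,
                          storeEvery = 48L, landMask = land)
  ages <- c(0.5, 1.5, 2.5, 3.5)
  ages <- ages[ages <= maxAge + 1e-9]
  fr <- classifyCoastalRecruits(traj, world@grid, ages, maxAge = maxAge)
  fr$cohort <- NULL # one drift season reused for every cohort
  abundanceField(world@hatchlings, fr, world@regions, world@years,
                 speciesCaps = caps, survivalAnnual = world@survivalAnnual)
}

#' Read abundance components written by the pipeline
#'
#' @param path abundance CSV (components layout).
#' @param survivalAnnual annual survival recorded in the manifest.
#' @return an \linkS4class{AbundanceField}.
#' @export
readAbundanceCsv <- function(path, survivalAnnual = 0.817) {
  a <- utils::read.csv(path)
  needCols(a, c("species", "year", "bin_lat", "bin_lon", "region", "age",
                "abundance"), "abundance CSV")
  new("AbundanceField", components = a, survivalAnnual = survivalAnnual)
}

#' Run the estimation pipeline over a simulated or supplied bundle
#'
#' Reads the input bundle from \code{cfg$outdir} (as written by
#' \code{\link{runSimulate}} or hand-assembled in the same schemas),
#' harmonizes effort, loads abundance, computes bycatch rates at the
#' appropriate granularity per gear (bin-level for commercial gears,
#' area-level for gears listed in \code{area_level_gears}), summarizes
#' them by geometric mean, extrapolates annual totals over the risk
#' indices, and writes every result table plus a run log with
#' record-exclusion accounting.
#'
#' @param cfg configuration from \code{\link{pipelineConfig}}.
#' @return invisibly, a list of the in-memory results (\code{effort},
#'   \code{abundance}, \code{rates}, \code{summary}, \code{risk},
#'   \code{estimates}, \code{annual}, \code{percent}, \code{trends}).
#' @export
runEstimate <- function(cfg) {
  outdir <- cfg$outdir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  memb <- stage("effort", utils::read.csv(file.path(outdir, "membership.csv")))
  gearFiles <- list.files(outdir, pattern = "^effort_.*\\.csv$",
                          full.names = TRUE)
  if (!length(gearFiles)) dataError("no raw effort tables in ", outdir)
  raw <- stats::setNames(lapply(gearFiles, utils::read.csv),
                         sub("^effort_(.*)\\.csv$", "\\1", basename(gearFiles)))
  harm <- stage("effort", harmonizeEffort(raw, memb))

  manifestPath <- file.path(outdir, "manifest.yaml")
  surv <- if (file.exists(manifestPath))
    yaml::read_yaml(manifestPath)$survival_annual else 0.817
  abund <- stage("recruitment",
                 readAbundanceCsv(file.path(outdir, "abundance.csv"), surv))

  byc <- stage("estimator", utils::read.csv(file.path(outdir, "bycatch.csv")))
  areaGears <- intersect(cfg$area_level_gears, unique(byc$gear))
  binGears <- setdiff(unique(byc$gear), areaGears)
  ratePieces <- list(); exclPieces <- list(); riskPieces <- list()
  if (length(binGears)) {
    rb <- stage("estimator", computeRates(byc[byc$gear %in% binGears, ],
                                          abund, harm, by = "bin"))
    ratePieces$bin <- rateTable(rb); exclPieces$bin <- excludedRecords(rb)
    rk <- riskIndices(abund, harm, by = "bin")
    riskPieces$bin <- rk[rk$gear %in% binGears, ]
  }
  if (length(areaGears)) {
    ra <- stage("estimator", computeRates(byc[byc$gear %in% areaGears, ],
                                          abund, harm, by = "area"))
    ratePieces$area <- rateTable(ra); exclPieces$area <- excludedRecords(ra)
    rk <- riskIndices(abund, harm, by = "area")
    riskPieces$area <- rk[rk$gear %in% areaGears, ]
  }
  rates <- do.call(rbind, ratePieces)
  excluded <- do.call(rbind, exclPieces)
  risk <- do.call(rbind, riskPieces)
  rownames(rates) <- rownames(risk) <- NULL

  summ <- stage("estimator", summarizeRates(rates))
  est <- stage("estimator", extrapolateBycatch(summ, risk))
  ann <- annualSummary(est)
  pct <- percentOfPopulation(est, abund)
  eTab <- estimateTable(est)
  trends <- do.call(rbind, lapply(split(eTab, list(eTab$species, eTab$gear),
                                        drop = TRUE), function(g) {
    tt <- trendTest(g$year, g$central)
    data.frame(species = g$species[1], gear = g$gear[1],
               r = tt$r, p = tt$p, n = tt$n)
  }))
  rownames(trends) <- NULL

  resdir <- file.path(outdir, "results")
  dir.create(resdir, showWarnings = FALSE)
  utils::write.csv(rates, file.path(resdir, "rates.csv"), row.names = FALSE)
  utils::write.csv(summaryTable(summ), file.path(resdir, "rate_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(formatRateSummary(summ),
                   file.path(resdir, "rate_table.csv"), row.names = FALSE)
  utils::write.csv(risk, file.path(resdir, "risk.csv"), row.names = FALSE)
  utils::write.csv(eTab, file.path(resdir, "estimates.csv"), row.names = FALSE)
  utils::write.csv(ann, file.path(resdir, "annual_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(pct, file.path(resdir, "percent_population.csv"),
                   row.names = FALSE)
  utils::write.csv(trends, file.path(resdir, "trends.csv"), row.names = FALSE)
  log <- c(paste0("turtleRisk ", as.character(utils::packageVersion("turtleRisk"))),
           paste0("seed: ", cfg$seed),
           paste0("years: ", min(cfg$years), "-", max(cfg$years)),
           paste0("rates computed: ", nrow(rates)),
           paste0("bycatch records excluded (T_b > 0 with zero T_p*F): ",
                  nrow(excluded)))
  writeLines(log, file.path(resdir, "run_log.txt"))
  invisible(list(effort = harm, abundance = abund, rates = rates,
                 excluded = excluded, summary = summ, risk = risk,
                 estimates = est, annual = ann, percent = pct,
                 trends = trends))
}
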