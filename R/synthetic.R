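#' @include AllClasses.R grid.R velocity.R effort.R recruitment.R
NULL

#' Construct the default synthetic study system
#'
#' A Gulf-of-Mexico-like system with a 1-degree grid (land north of the
#' coastal row), a 16-bin coastline partitioned into six state/area
#' labels (Texas spanning 4 bins, Mississippi a single bin, mirroring the
#' real coastline's bin counts), two species with four nesting regions, a
#' double-gyre surface flow, and three fisheries with known constant
#' catchability. All downstream inputs (velocity, effort, abundance,
#' bycatch) are generated from this object deterministically given its
#' seed.
#'
#' Defaults: 350 particles/day over a 60-day emergence window; annual
#' oceanic survival 0.817; species drift caps 2.5 yr (Kemp's ridley) and
#' 3.5 yr (green); ten study years. Hatchling production and effort carry
#' a linear annual trend with multiplicative lognormal noise (keeps both
#' positive).
#'
#' @param seed root integer seed.
#' @param years study years (default 1996:2005).
#' @param qTrue optional named override of true catchabilities; a
#'   data.frame \code{species}, \code{gear}, \code{q}.
#' @param effortNoiseSd lognormal sd of effort noise (default 0.15).
#' @param effortSlopes named per-gear annual trend slopes (fraction/yr).
#' @param flow flow spec list (name + parameters); default a mildly
#'   time-dependent double gyre spanning the grid.
#' @return a \linkS4class{SyntheticWorld}.
#' @export
makeSyntheticWorld <- function(seed = 1L, years = 1996:2005,
                               qTrue = NULL, effortNoiseSd = 0.15,
                               effortSlopes = c(shrimp_trawl = -0.03,
                                                gillnet = 0.02,
                                                recreational = 0.02),
                               flow = NULL) {
  seed <- as.integer(seed)
  years <- as.integer(years)
  ## grid: lon -98..-82, lat 23..30; coast at lat bin 28, land above
  cells <- expand.grid(bin_lat = 23:30, bin_lon = -98:-82,
                       KEEP.OUT.ATTRS = FALSE)
  cells$coastal <- cells$bin_lat == 28L & cells$bin_lon >= -97L
  areaOf <- function(lon) {
    cut(lon, breaks = c(-97.5, -93.5, -90.5, -89.5, -87.5, -84.5, -81.5),
        labels = c("TX", "LA", "MS", "AL", "WFL", "EFL"))
  }
  cells$area <- ifelse(cells$coastal, as.character(areaOf(cells$bin_lon)),
                       NA_character_)
  grid <- binGrid(cells)

  regions <- data.frame(
    region = c("kemps_west", "kemps_south", "green_east", "green_south"),
    species = c("kemps_ridley", "kemps_ridley", "green", "green"),
    lon = c(-96.5, -92.5, -83.5, -88.5),
    lat = c(25.5, 24.5, 24.5, 23.5),
    window_start = 0)

  species <- data.frame(species = c("kemps_ridley", "green"),
                        max_age = c(2.5, 3.5))

  ## hatchling production: linear growth + lognormal noise, cohorts far
  ## enough back to cover the oldest age class in the first study year
  hYears <- (min(years) - 4L):max(years)
  base <- c(kemps_west = 1e5, kemps_south = 8e4,
            green_east = 2e5, green_south = 1.5e5)
  set.seed(childSeed(seed, 1L))
  hatch <- expand.grid(region = names(base), year = hYears,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sdH <- 0.1
  hatch$H <- base[hatch$region] *
    (1 + 0.03 * (hatch$year - min(hYears))) *
    exp(stats::rnorm(nrow(hatch), -sdH^2 / 2, sdH))

  if (is.null(flow))
    flow <- list(name = "double_gyre", A = 2, eps = 0.1,
                 omega = 2 * pi / 30, lon0 = -98, lat0 = 23, width = 16)

  if (is.null(qTrue))
    qTrue <- data.frame(
      species = rep(c("kemps_ridley", "green"), each = 3),
      gear = rep(c("shrimp_trawl", "gillnet", "recreational"), 2),
      q = c(2e-6, 2e-4, 4e-6,
            1e-6, 1e-4, 2e-6))

  effortSpec <- list(
    shrimp_trawl = list(base = 1200, slope = unname(effortSlopes["shrimp_trawl"]),
                        sdlog = effortNoiseSd),
    gillnet = list(base = 3000, slope = unname(effortSlopes["gillnet"]),
                   sdlog = effortNoiseSd, set_length_km = 2, soak_days = 0.3),
    recreational = list(base = 6e5, slope = unname(effortSlopes["recreational"]),
                        sdlog = effortNoiseSd))

  new("SyntheticWorld", grid = grid, regions = regions, hatchlings = hatch,
      flow = flow, species = species, catchability = qTrue,
      effortSpec = effortSpec, years = years, survivalAnnual = 0.817,
      releasesPerDay = 350, windowDays = 60, seed = seed)
}

#' Generate the synthetic world's velocity field
#'
#' Evaluates the world's analytic flow on the world grid's node lattice
#' over \code{days} daily snapshots.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param days number of daily time steps (default enough for one cohort
#'   drift season; pass more for multi-year drifts).
#' @return a \linkS4class{VelocityField}.
#' @export
genWorldVelocity <- function(world, days = 120) {
  b <- bins(world@grid)
  lon <- seq(min(b$bin_lon), max(b$bin_lon) + 1L)
  lat <- seq(min(b$bin_lat), max(b$bin_lat) + 1L)
  fl <- world@flow
  genVelocityField(fl$name, fl[setdiff(names(fl), "name")],
                   lon = lon, lat = lat, times = 0:(days - 1))
}

#' Generate raw per-gear effort tables
#'
#' One table per gear in that gear's native units, with a linear annual
#' trend and multiplicative lognormal noise; spatial allocation across
#' areas is proportional to each area's coastline bin count, so per-bin
#' intensity is uniform at the trend line.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param years subset of world years (default all).
#' @return named list of raw effort data.frames in the schemas accepted
#'   by \code{\link{harmonizeEffort}}.
#' @export
genEffort <- function(world, years = world@years) {
  if (length(years) == 0L) configError("years must be non-empty")
  memb <- areaMembership(world@grid)
  nb <- table(memb$area)
  w <- as.vector(nb) / sum(nb)
  names(w) <- names(nb)
  y0 <- min(world@years)
  set.seed(childSeed(world@seed, 2L))
  out <- list()
  for (g in names(world@effortSpec)) {
    sp <- world@effortSpec[[g]]
    tab <- expand.grid(area = names(w), year = years,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    noise <- if (sp$sdlog > 0)
      exp(stats::rnorm(nrow(tab), -sp$sdlog^2 / 2, sp$sdlog)) else 1
    level <- sp$base * w[tab$area] * (1 + sp$slope * (tab$year - y0)) * noise
    level <- pmax(level, 0)
    out[[g]] <- switch(g,
      shrimp_trawl = data.frame(year = tab$year, area = tab$area,
                                basin = "gulf", days_trawled = unname(level)),
      gillnet = data.frame(year = tab$year, area = tab$area,
                           set_length_km = sp$set_length_km,
                           n_sets = unname(level), soak_days = sp$soak_days),
      recreational = data.frame(year = tab$year, area = tab$area,
                                angler_trips = unname(level)),
      longline = data.frame(year = tab$year, area = tab$area,
                            set_length_km = sp$set_length_km,
                            n_sets = unname(level)),
      hookline = data.frame(year = tab$year, area = tab$area,
                            n_lines = unname(level), hours = sp$hours))
  }
  out
}

#' Deterministic coastal recruitment fractions of the synthetic world
#'
#' A closed-form stand-in for running the full drift simulation: each
#' region's recruits are spread over the coastal bins with exponential
#' decay in alongshore distance from the region (length scale
#' \code{decayLength} degrees), and total coastal mass declines with age.
#' Used by \code{\link{genAbundance}}; the advection-based path is
#' exercised through \code{\link{advectParticles}} +
#' \code{\link{classifyCoastalRecruits}}.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param ages age classes (default 0.5, 1.5, 2.5, 3.5 yr).
#' @param coastalMass total coastal fraction per age class.
#' @param decayLength alongshore e-folding scale in degrees.
#' @return data.frame \code{region}, \code{age}, \code{bin_lat},
#'   \code{bin_lon}, \code{p} (cohort-invariant).
#' @export
syntheticRecruitFractions <- function(world, ages = c(0.5, 1.5, 2.5, 3.5),
                                      coastalMass = c(0.35, 0.25, 0.15, 0.08),
                                      decayLength = 12) {
  cb <- coastalBins(world@grid)
  out <- list()
  for (i in seq_len(nrow(world@regions))) {
    r <- world@regions[i, ]
    wgt <- exp(-abs(cb$bin_lon + 0.5 - r$lon) / decayLength)
    wgt <- wgt / sum(wgt)
    for (j in seq_along(ages)) {
      out[[length(out) + 1L]] <- data.frame(
        region = r$region, age = ages[j],
        bin_lat = cb$bin_lat, bin_lon = cb$bin_lon,
        p = coastalMass[j] * wgt)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate the synthetic abundance field
#'
#' Hatchling production x synthetic recruitment fractions x survival
#' scaling, through the same \code{\link{abundanceField}} operation the
#' real pipeline uses.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param years calendar years (default world years).
#' @return an \linkS4class{AbundanceField}.
#' @export
genAbundance <- function(world, years = world@years) {
  caps <- stats::setNames(world@species$max_age, world@species$species)
  abundanceField(world@hatchlings, syntheticRecruitFractions(world),
                 world@regions, years, speciesCaps = caps,
                 survivalAnnual = world@survivalAnnual)
}

#' Expected bycatch means of the synthetic observation model
#'
#' The Poisson mean \code{lambda = q_true * T_p * F} for every species,
#' gear, year and bin, from the ground truth. Useful for audits of the
#' generated data (e.g. verifying that observed bins are data-rich).
#'
#' @param abundance an \linkS4class{AbundanceField}.
#' @param effort a \linkS4class{HarmonizedEffort}.
#' @param catchability data.frame \code{species}, \code{gear}, \code{q}.
#' @return data.frame \code{species}, \code{gear}, \code{year},
#'   \code{area}, \code{bin_lat}, \code{bin_lon}, \code{t_p}, \code{f},
#'   \code{lambda}.
#' @export
trueBycatchMeans <- function(abundance, effort, catchability) {
  if (any(catchability$q < 0)) configError("q_true must be >= 0")
  tp <- abundanceGrid(abundance)
  ef <- effortTable(effort)
  if (!length(intersect(unique(tp$year), unique(ef$year))))
    dataError("abundance and effort share no years (alignment error)")
  ef <- merge(ef, data.frame(species = unique(catchability$species)))
  m <- merge(ef, tp, by = c("species", "year", "bin_lat", "bin_lon"),
             all.x = TRUE)
  m$t_p[is.na(m$t_p)] <- 0 # bins the drift model never reaches
  m <- merge(m, catchability, by = c("species", "gear"))
  m$lambda <- m$q * m$t_p * m$effort
  data.frame(species = m$species, gear = m$gear, year = m$year,
             area = m$area, bin_lat = m$bin_lat, bin_lon = m$bin_lon,
             t_p = m$t_p, f = m$effort, lambda = m$lambda)
}

#' Generate observed-bycatch records
#'
#' Per species, gear, year and bin, the observed count is a Poisson draw
#' with mean \code{q_true * T_p * F}. Cells with zero mean yield zero
#' counts; zero-count rows are retained (the estimator excludes them).
#'
#' @inheritParams trueBycatchMeans
#' @param seed integer seed for the draws.
#' @return data.frame \code{species}, \code{gear}, \code{year},
#'   \code{area}, \code{bin_lat}, \code{bin_lon}, \code{count}.
#' @export
genBycatch <- function(abundance, effort, catchability, seed) {
  lam <- trueBycatchMeans(abundance, effort, catchability)
  set.seed(as.integer(seed))
  lam$count <- stats::rpois(nrow(lam), lam$lambda)
  lam[, c("species", "gear", "year", "area", "bin_lat", "bin_lon", "count")]
}
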