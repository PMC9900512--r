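#' @include AllClasses.R grid.R utils.R
NULL

#' Trawl distance covered per day of trawling, by basin
#'
#' Typical trawling speeds expressed as km/day: 2.9 knots in the Gulf of
#' Mexico, 2.6 knots in the Atlantic. The printed km/day constants are
#' used directly (not recomputed from knots) so converted effort matches
#' the published series bit for bit; \code{\link{knotsToKmPerDay}} keeps
#' the derivation available.
#' @export
TRAWL_KM_PER_DAY <- c(gulf = 128.9, atlantic = 115.6)

#' Default soak time assumed for bottom longlines: 5 hours in days
#' @export
LONGLINE_SOAK_DAYS <- 0.2083

#' Gulf-to-Atlantic shrimping back-extrapolation multiplier
#'
#' Atlantic shrimping effort averaged 77.5\% less than the Gulf of Mexico
#' over the overlapping years, hence the multiplier 1 - 0.775 = 0.225.
#' @export
ATLANTIC_SHRIMP_MULTIPLIER <- 0.225

#' Atlantic shrimping spatial partition weights
#'
#' Shares of Atlantic-wide shrimping effort assigned to each subregion,
#' proportional to trips per statistical zone. The published weights sum
#' to 0.999 and are applied without renormalization. An alternative set
#' based on observer-monitored trips is provided for sensitivity checks.
#' @export
ATLANTIC_SHRIMP_WEIGHTS <- c(EFL = 0.085, GA = 0.189, SC = 0.360, NC = 0.365)

#' @rdname ATLANTIC_SHRIMP_WEIGHTS
#' @export
ATLANTIC_SHRIMP_WEIGHTS_OBSERVER <-
  c(EFL = 0.418, GA = 0.139, SC = 0.177, NC = 0.266)

#' Mean recreational fishing-trip duration per state, in hours
#' @export
REC_TRIP_HOURS <- c(TX = 5.6, LA = 4.1, MS = 3.5, AL = 3.4, WFL = 3.9,
                    EFL = 3.8, GA = 3.6, SC = 3.0, NC = 2.4, VA = 3.2)

#' Convert knots to km/day
#'
#' @param knots speed in knots (nautical miles per hour; 1 nmi = 1.852 km).
#' @return km travelled per 24 h day.
#' @examples
#' knotsToKmPerDay(2.9) # ~128.9
#' @export
knotsToKmPerDay <- function(knots) knots * 1.852 * 24

#' Convert days trawled to km trawled
#'
#' One day trawled is 24 h of actual trawling by one vessel; distance uses
#' the basin's typical trawl speed (see \code{\link{TRAWL_KM_PER_DAY}}).
#'
#' @param days days trawled (>= 0), vectorized.
#' @param basin "gulf" or "atlantic", recycled.
#' @return km trawled.
#' @export
convertTrawlEffort <- function(days, basin) {
  if (any(days < 0)) dataError("days trawled must be non-negative")
  basin <- rep_len(as.character(basin), length(days))
  if (!all(basin %in% names(TRAWL_KM_PER_DAY)))
    configError("unknown basin: ",
                paste(setdiff(basin, names(TRAWL_KM_PER_DAY)), collapse = ", "))
  days * unname(TRAWL_KM_PER_DAY[basin])
}

#' Back-extrapolate the Atlantic shrimping series from the Gulf series
#'
#' Years missing from the Atlantic series are filled as
#' \code{multiplier x gulf}; observed Atlantic years pass through
#' unchanged.
#'
#' @param gulf data.frame \code{year}, \code{effort} (Gulf-wide annual).
#' @param atlantic data.frame \code{year}, \code{effort} (observed
#'   Atlantic years).
#' @param backfillYears years to fill (must be present in \code{gulf}).
#' @param multiplier default \code{\link{ATLANTIC_SHRIMP_MULTIPLIER}}.
#' @return data.frame \code{year}, \code{effort}, \code{backfilled}.
#' @export
extendAtlanticShrimp <- function(gulf, atlantic, backfillYears,
                                 multiplier = ATLANTIC_SHRIMP_MULTIPLIER) {
  needCols(gulf, c("year", "effort"), "gulf series")
  needCols(atlantic, c("year", "effort"), "atlantic series")
  miss <- setdiff(backfillYears, gulf$year)
  if (length(miss))
    dataError("gulf series lacks back-fill year(s): ",
              paste(miss, collapse = ", "))
  filled <- data.frame(
    year = backfillYears,
    effort = multiplier * gulf$effort[match(backfillYears, gulf$year)],
    backfilled = TRUE)
  obs <- data.frame(year = atlantic$year, effort = atlantic$effort,
                    backfilled = FALSE)
  out <- rbind(filled[!filled$year %in% obs$year, ], obs)
  out[order(out$year), ]
}

#' Partition Atlantic-wide shrimping effort into subregions
#'
#' Subregion effort is \code{total x weight}; the default weights sum to
#' 0.999 and are deliberately not renormalized.
#'
#' @param total Atlantic-wide effort (scalar or per-year vector).
#' @param weights named non-negative weights (default
#'   \code{\link{ATLANTIC_SHRIMP_WEIGHTS}}).
#' @return data.frame \code{area}, \code{effort} (one block per element of
#'   \code{total}, with a \code{year}-preserving \code{index} column when
#'   \code{total} has length > 1).
#' @export
partitionAtlanticShrimp <- function(total, weights = ATLANTIC_SHRIMP_WEIGHTS) {
  if (any(weights < 0)) configError("partition weights must be non-negative")
  out <- data.frame(
    index = rep(seq_along(total), each = length(weights)),
    area = rep(names(weights), times = length(total)),
    effort = as.vector(outer(unname(weights), total)))
  if (length(total) == 1L) out$index <- NULL
  out
}

#' Partition a Gulf-wide total by a prior year's area distribution
#'
#' When only a basin-wide total is available for the latest year, it is
#' split across areas in proportion to the prior year's per-area
#' distribution; shares sum to the total exactly.
#'
#' @param total Gulf-wide effort for the year to partition.
#' @param prior named numeric of per-area effort in the reference year.
#' @return named numeric of per-area effort summing to \code{total}.
#' @export
partitionGulfLatestYear <- function(total, prior) {
  s <- sum(prior)
  if (!is.finite(s) || s <= 0)
    dataError("prior-year distribution is degenerate (sum <= 0)")
  total * prior / s
}

#' Longline effort in km.days
#'
#' Mean set length times number of sets times soak time. Soak defaults to
#' the assumed 5 h (0.2083 days) typical of bottom longlining.
#'
#' @param setLengthKm mean set length (km).
#' @param nSets number of sets.
#' @param soakDays soak time in days (default
#'   \code{\link{LONGLINE_SOAK_DAYS}}).
#' @return effort in km.days.
#' @export
longlineEffort <- function(setLengthKm, nSets, soakDays = LONGLINE_SOAK_DAYS) {
  if (any(setLengthKm < 0) || any(nSets < 0) || any(soakDays < 0))
    dataError("longline effort inputs must be non-negative")
  setLengthKm * nSets * soakDays
}

#' Gillnet effort in km.days
#'
#' Same formula as \code{\link{longlineEffort}} but with the reported,
#' not assumed, soak time.
#'
#' @param setLengthKm mean set length (km).
#' @param nSets number of sets.
#' @param soakDays reported soak time in days.
#' @return effort in km.days.
#' @export
gillnetEffort <- function(setLengthKm, nSets, soakDays) {
  if (any(setLengthKm < 0) || any(nSets < 0) || any(soakDays < 0))
    dataError("gillnet effort inputs must be non-negative")
  setLengthKm * nSets * soakDays
}

#' Hook-and-line effort in line.days
#'
#' @param nLines number of lines.
#' @param hours hours fished (converted to days).
#' @return effort in line.days.
#' @export
hooklineEffort <- function(nLines, hours) {
  if (any(nLines < 0) || any(hours < 0))
    dataError("hook-and-line effort inputs must be non-negative")
  nLines * hours / 24
}

#' Recreational effort in angler.days
#'
#' Angler trips times the state's mean trip duration, expressed in days.
#'
#' @param trips number of angler trips, vectorized.
#' @param state state/subregion code, recycled; must appear in
#'   \code{durations}.
#' @param durations named mean trip duration in hours per state (default
#'   \code{\link{REC_TRIP_HOURS}}).
#' @return effort in angler.days.
#' @examples
#' recreationalEffort(24, "TX") # 5.6 angler.days
#' @export
recreationalEffort <- function(trips, state, durations = REC_TRIP_HOURS) {
  if (any(trips < 0)) dataError("angler trips must be non-negative")
  state <- rep_len(as.character(state), length(trips))
  if (!all(state %in% names(durations)))
    configError("unknown state(s): ",
                paste(setdiff(state, names(durations)), collapse = ", "))
  trips * unname(durations[state]) / 24
}

#' Spread area-level effort evenly across the area's bins
#'
#' Effort reported for a state/area is divided by the number of 1-degree
#' bins across that part of the coastline, each member bin receiving an
#' equal share; single-bin areas pass through unchanged and area totals
#' are conserved exactly.
#'
#' @param areaEffort data.frame: \code{gear}, \code{year}, \code{area},
#'   \code{effort}, \code{unit}.
#' @param membership data.frame: \code{area}, \code{bin_lat},
#'   \code{bin_lon} (from \code{\link{areaMembership}} or user-supplied).
#' @return a \linkS4class{HarmonizedEffort}.
#' @export
rasterizeEffort <- function(areaEffort, membership) {
  needCols(areaEffort, c("gear", "year", "area", "effort", "unit"),
           "area-level effort")
  needCols(membership, c("area", "bin_lat", "bin_lon"), "bin membership")
  unmapped <- setdiff(unique(areaEffort$area), unique(membership$area))
  if (length(unmapped))
    configError("area label(s) with no bin membership: ",
                paste(unmapped, collapse = ", "))
  nb <- table(membership$area)
  m <- merge(areaEffort, membership, by = "area")
  m$effort <- m$effort / as.vector(nb[m$area])
  ## collapse in case several area rows land in the same (gear, year, bin)
  out <- stats::aggregate(
    list(effort = m$effort),
    by = list(gear = m$gear, year = m$year, area = m$area,
              bin_lat = m$bin_lat, bin_lon = m$bin_lon, unit = m$unit),
    FUN = sum)
  out <- out[order(out$gear, out$year, out$bin_lat, out$bin_lon),
             c("gear", "year", "area", "bin_lat", "bin_lon", "effort", "unit")]
  rownames(out) <- NULL
  new("HarmonizedEffort", effort = out)
}

## standard exposure unit per gear
GEAR_UNITS <- c(shrimp_trawl = "km", longline = "km_days",
                gillnet = "km_days", hookline = "line_days",
                recreational = "angler_days")

#' Harmonize raw multi-gear effort tables
#'
#' Applies each gear's unit conversion to its raw table, then spreads the
#' area-level results across bins. Raw schemas per gear:
#' \describe{
#'   \item{shrimp_trawl}{\code{year, area, basin, days_trawled}}
#'   \item{longline}{\code{year, area, set_length_km, n_sets} (+ optional
#'     \code{soak_days})}
#'   \item{gillnet}{\code{year, area, set_length_km, n_sets, soak_days}}
#'   \item{hookline}{\code{year, area, n_lines, hours}}
#'   \item{recreational}{\code{year, area, angler_trips} (area is the
#'     state code)}
#' }
#'
#' @param raw named list of raw data.frames, names in
#'   \code{names(GEAR_UNITS)}.
#' @param membership area-to-bin membership data.frame.
#' @param recDurations state trip-duration table for recreational effort.
#' @return a \linkS4class{HarmonizedEffort} covering all gears.
#' @export
harmonizeEffort <- function(raw, membership, recDurations = REC_TRIP_HOURS) {
  unknown <- setdiff(names(raw), names(GEAR_UNITS))
  if (length(unknown))
    configError("unknown gear(s): ", paste(unknown, collapse = ", "))
  pieces <- lapply(names(raw), function(g) {
    r <- raw[[g]]
    eff <- switch(g,
      shrimp_trawl = {
        needCols(r, c("year", "area", "basin", "days_trawled"), g)
        convertTrawlEffort(r$days_trawled, r$basin)
      },
      longline = {
        needCols(r, c("year", "area", "set_length_km", "n_sets"), g)
        soak <- if ("soak_days" %in% names(r)) r$soak_days else LONGLINE_SOAK_DAYS
        longlineEffort(r$set_length_km, r$n_sets, soak)
      },
      gillnet = {
        needCols(r, c("year", "area", "set_length_km", "n_sets", "soak_days"), g)
        gillnetEffort(r$set_length_km, r$n_sets, r$soak_days)
      },
      hookline = {
        needCols(r, c("year", "area", "n_lines", "hours"), g)
        hooklineEffort(r$n_lines, r$hours)
      },
      recreational = {
        needCols(r, c("year", "area", "angler_trips"), g)
        recreationalEffort(r$angler_trips, r$area, recDurations)
      })
    data.frame(gear = g, year = r$year, area = r$area, effort = eff,
               unit = unname(GEAR_UNITS[g]))
  })
  rasterizeEffort(do.call(rbind, pieces), membership)
}

#' Write / read a harmonized effort table
#'
#' @param x a \linkS4class{HarmonizedEffort}.
#' @param path CSV path.
#' @return \code{readEffortCsv} returns a \linkS4class{HarmonizedEffort}.
#' @export
writeEffortCsv <- function(x, path) {
  utils::write.csv(effortTable(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEffortCsv
#' @export
readEffortCsv <- function(path) {
  e <- utils::read.csv(path)
  needCols(e, c("gear", "year", "area", "bin_lat", "bin_lon", "effort", "unit"),
           "effort CSV")
  new("HarmonizedEffort", effort = e)
}
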