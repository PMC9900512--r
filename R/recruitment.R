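#' @include AllClasses.R advection.R grid.R
NULL

#' Days per year used for age arithmetic
#' @keywords internal
DAYS_PER_YEAR <- 365.25

#' Total particles released per region-year
#'
#' @param perDay particles released per day (default 350).
#' @param windowDays length of the emergence window in days (default 60).
#' @return \code{perDay * windowDays} (21,000 at the defaults).
#' @examples
#' countReleases() # 21000
#' @export
countReleases <- function(perDay = 350, windowDays = 60) {
  stopifnot(perDay >= 0, windowDays >= 0)
  perDay * windowDays
}

#' Build a release schedule for one cohort
#'
#' \code{perDay} particles are released at the region's release point on
#' each of \code{windowDays} consecutive days starting at
#' \code{windowStart}.
#'
#' @param regions data.frame: \code{region}, \code{lon}, \code{lat},
#'   optional \code{window_start} (day offset on the velocity time axis;
#'   default 0).
#' @param cohort cohort year label.
#' @param perDay,windowDays release intensity and window length.
#' @return data.frame suitable for \code{\link{advectParticles}}:
#'   \code{region}, \code{cohort}, \code{lon0}, \code{lat0}, \code{t0}.
#' @export
makeReleaseSchedule <- function(regions, cohort, perDay = 350, windowDays = 60) {
  needCols(regions, c("region", "lon", "lat"), "regions")
  ws <- if ("window_start" %in% names(regions)) regions$window_start else 0
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    days <- rep(seq_len(windowDays) - 1L, each = perDay)
    data.frame(region = regions$region[i], cohort = cohort,
               lon0 = regions$lon[i], lat0 = regions$lat[i],
               t0 = rep_len(ws, nrow(regions))[i] + days)
  }))
  rownames(out) <- NULL
  out
}

#' Classify coastal recruits and compute recruitment fractions
#'
#' At each requested age, each particle's position (nearest stored step to
#' \code{age * 365.25} days since its release) is assigned to a 1-degree
#' bin; particles falling in a coastal bin are "coastal recruits". The
#' fraction is the number of recruits in a bin divided by the number of
#' particles released from that region-cohort, so fractions over coastal
#' bins sum to at most 1.
#'
#' @param traj a \linkS4class{Trajectories}.
#' @param grid a \linkS4class{BinGrid} with coastal flags.
#' @param ages numeric age classes in years (e.g. \code{c(0.5, 1.5)}).
#' @param maxAge optional species drift cap in years; requesting an age
#'   beyond it is a contract error.
#' @return data.frame: \code{region}, \code{cohort}, \code{age},
#'   \code{bin_lat}, \code{bin_lon}, \code{p}.
#' @export
classifyCoastalRecruits <- function(traj, grid, ages, maxAge = NULL) {
  if (!is.null(maxAge) && any(ages > maxAge + 1e-9))
    configError("requested age exceeds the species drift cap (", maxAge, " yr)")
  cb <- coastalBins(grid)
  coastKeys <- binKey(cb$bin_lat, cb$bin_lon)
  rel <- traj@releases
  nRel <- stats::aggregate(list(n = rel$id),
                           by = list(region = rel$region, cohort = rel$cohort),
                           FUN = length)
  out <- list()
  for (a in ages) {
    pos <- positionsAtAge(traj, a * DAYS_PER_YEAR)
    b <- latLonToBin(pos$lat, pos$lon)
    pos$bin_lat <- b$bin_lat; pos$bin_lon <- b$bin_lon
    pos <- pos[!is.na(pos$bin_lat) &
                 binKey(pos$bin_lat, pos$bin_lon) %in% coastKeys, ]
    if (nrow(pos) == 0L) next
    cnt <- stats::aggregate(
      list(k = pos$id),
      by = list(region = pos$region, cohort = pos$cohort,
                bin_lat = pos$bin_lat, bin_lon = pos$bin_lon),
      FUN = length)
    cnt <- merge(cnt, nRel, by = c("region", "cohort"))
    cnt$age <- a
    cnt$p <- cnt$k / cnt$n
    out[[length(out) + 1L]] <-
      cnt[, c("region", "cohort", "age", "bin_lat", "bin_lon", "p")]
  }
  if (!length(out))
    return(data.frame(region = character(), cohort = integer(),
                      age = numeric(), bin_lat = integer(),
                      bin_lon = integer(), p = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Daily oceanic survival from an annual rate
#'
#' @param annual annual survival probability (default 0.817, the median
#'   oceanic-stage estimate).
#' @return per-day survival \code{annual^(1/365)}.
#' @examples
#' dailySurvival()^365 # 0.817
#' @export
dailySurvival <- function(annual = 0.817) {
  stopifnot(annual > 0, annual <= 1)
  annual^(1 / 365)
}

#' Predicted coastal juvenile abundance from recruitment fractions
#'
#' For each bin, calendar year, nesting region and age class, abundance is
#' hatchling production of the contributing cohort times the coastal
#' recruitment fraction times cumulative oceanic survival to that age
#' (applied as the daily rate compounded over \code{365 * age} days, i.e.
#' \code{annual^age}). A turtle of age \code{a} counted in calendar year
#' \code{y} belongs to the cohort hatched in year \code{y - ceiling(a)};
#' pass \code{cohortOffset} to change that convention. Components are
#' summed over regions and ages per species; species drift caps limit the
#' ages used.
#'
#' @param hatchlings data.frame: \code{region}, \code{year}, \code{H}.
#' @param fractions recruitment fractions as from
#'   \code{\link{classifyCoastalRecruits}}; if no \code{cohort} column is
#'   present the fractions are treated as cohort-invariant.
#' @param regions data.frame mapping \code{region} to \code{species}.
#' @param years calendar years to predict.
#' @param speciesCaps named numeric, max drift age per species in years
#'   (e.g. \code{c(kemps_ridley = 2.5, green = 3.5)}).
#' @param ages age classes in years (default \code{c(0.5, 1.5, 2.5, 3.5)}).
#' @param survivalAnnual annual oceanic survival (default 0.817).
#' @param cohortOffset function age -> years subtracted from the calendar
#'   year to find the hatch cohort (default \code{ceiling}).
#' @return an \linkS4class{AbundanceField}. A needed cohort year missing
#'   from \code{hatchlings} is an error, never a silent zero.
#' @export
abundanceField <- function(hatchlings, fractions, regions, years,
                           speciesCaps, ages = c(0.5, 1.5, 2.5, 3.5),
                           survivalAnnual = 0.817,
                           cohortOffset = ceiling) {
  needCols(hatchlings, c("region", "year", "H"), "hatchlings")
  needCols(regions, c("region", "species"), "regions")
  needCols(fractions, c("region", "age", "bin_lat", "bin_lon", "p"), "fractions")
  cohortFree <- !"cohort" %in% names(fractions)
  hKey <- paste(hatchlings$region, hatchlings$year)
  comp <- list()
  for (y in years) {
    for (a in ages) {
      cohort <- y - cohortOffset(a)
      fr <- fractions[abs(fractions$age - a) < 1e-9, , drop = FALSE]
      if (!cohortFree) fr <- fr[fr$cohort == cohort, , drop = FALSE]
      if (nrow(fr) == 0L) next
      sp <- regions$species[match(fr$region, regions$region)]
      cap <- speciesCaps[sp]
      fr <- fr[!is.na(cap) & a <= cap + 1e-9, , drop = FALSE]
      if (nrow(fr) == 0L) next
      hIdx <- match(paste(fr$region, cohort), hKey)
      if (anyNA(hIdx))
        dataError("missing hatchling production for region(s) ",
                  paste(unique(fr$region[is.na(hIdx)]), collapse = ", "),
                  " cohort year ", cohort)
      comp[[length(comp) + 1L]] <- data.frame(
        species = regions$species[match(fr$region, regions$region)],
        year = y, bin_lat = fr$bin_lat, bin_lon = fr$bin_lon,
        region = fr$region, age = a,
        abundance = hatchlings$H[hIdx] * fr$p * survivalAnnual^a)
    }
  }
  comps <- if (length(comp)) do.call(rbind, comp) else
    data.frame(species = character(), year = integer(), bin_lat = integer(),
               bin_lon = integer(), region = character(), age = numeric(),
               abundance = numeric())
  rownames(comps) <- NULL
  new("AbundanceField", components = comps, survivalAnnual = survivalAnnual)
}

#' Total abundance per bin-year (components summed over age and region)
#'
#' @param x an \linkS4class{AbundanceField}.
#' @param ... unused.
#' @return data.frame \code{species}, \code{year}, \code{bin_lat},
#'   \code{bin_lon}, \code{t_p}.
#' @export
setMethod("abundanceGrid", "AbundanceField", function(x, ...) {
  a <- x@components
  if (nrow(a) == 0L)
    return(data.frame(species = character(), year = integer(),
                      bin_lat = integer(), bin_lon = integer(),
                      t_p = numeric()))
  g <- stats::aggregate(
    list(t_p = a$abundance),
    by = list(species = a$species, year = a$year,
              bin_lat = a$bin_lat, bin_lon = a$bin_lon),
    FUN = sum)
  g[order(g$species, g$year, g$bin_lat, g$bin_lon), , drop = FALSE]
})

#' Age composition of coastal recruitment
#'
#' Per species and year, the percentage of total coastal abundance in each
#' age class. Rows sum to 100.
#'
#' @param x an \linkS4class{AbundanceField}.
#' @return data.frame \code{species}, \code{year}, \code{age},
#'   \code{percent}.
#' @export
ageComposition <- function(x) {
  a <- abundanceComponents(x)
  byAge <- stats::aggregate(list(abund = a$abundance),
                            by = list(species = a$species, year = a$year,
                                      age = a$age), FUN = sum)
  tot <- stats::aggregate(list(total = byAge$abund),
                          by = list(species = byAge$species,
                                    year = byAge$year), FUN = sum)
  m <- merge(byAge, tot, by = c("species", "year"))
  m$percent <- 100 * m$abund / m$total
  m <- m[order(m$species, m$year, m$age),
         c("species", "year", "age", "percent")]
  rownames(m) <- NULL
  m
}
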