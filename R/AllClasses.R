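#' @import methods
NULL

#' BinGrid: the 1-degree spatial reference grid
#'
#' A set of 1 x 1 degree cells identified by the integer floor of latitude
#' and longitude (half-open bounds \code{[lat, lat+1) x [lon, lon+1)}), each
#' carrying a coastal flag and an area/state membership label. All spatial
#' joins in the pipeline key on these bins.
#'
#' @slot bins data.frame with columns \code{bin_lat}, \code{bin_lon}
#'   (integers), \code{coastal} (logical) and \code{area} (character,
#'   \code{NA} for bins outside any managed area).
#' @export
setClass("BinGrid", representation(bins = "data.frame"))

setValidity("BinGrid", function(object) {
  b <- object@bins
  req <- c("bin_lat", "bin_lon", "coastal", "area")
  if (!all(req %in% names(b)))
    return(paste("bins must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(b[, c("bin_lat", "bin_lon")]))
    return("bin ids must be unique")
  if (!is.logical(b$coastal)) return("coastal must be logical")
  if (any(b$bin_lat != floor(b$bin_lat)) || any(b$bin_lon != floor(b$bin_lon)))
    return("bin ids must be integer floors of lat/lon")
  TRUE
})

#' VelocityField: gridded surface-velocity time series
#'
#' Zonal (u) and meridional (v) velocity on a regular lon/lat grid at a
#' series of time points, the driver of passive particle drift. Analytic
#' generators produce fields directly in degrees/day; fields read from
#' ocean-model exports in m/s are converted during advection.
#'
#' @slot lon,lat numeric grid-node coordinates (strictly increasing).
#' @slot time numeric time points in days (strictly increasing).
#' @slot u,v numeric arrays of dim \code{c(nlon, nlat, ntime)}.
#' @slot units "deg_day" or "m_s".
#' @export
setClass("VelocityField", representation(
  lon = "numeric", lat = "numeric", time = "numeric",
  u = "array", v = "array", units = "character"))

setValidity("VelocityField", function(object) {
  d <- c(length(object@lon), length(object@lat), length(object@time))
  if (!identical(dim(object@u), d) || !identical(dim(object@v), d))
    return("u and v must have dim c(nlon, nlat, ntime)")
  if (is.unsorted(object@lon, strictly = TRUE) ||
      is.unsorted(object@lat, strictly = TRUE) ||
      is.unsorted(object@time, strictly = TRUE))
    return("lon, lat and time must be strictly increasing")
  if (!object@units %in% c("deg_day", "m_s"))
    return("units must be 'deg_day' or 'm_s'")
  if (any(!is.finite(object@u)) || any(!is.finite(object@v)))
    return("velocities must be finite")
  TRUE
})

#' Trajectories: particle tracks from the advection kernel
#'
#' Positions of every released particle at stored time steps on a common
#' time axis. Particles that leave the grid or hit land are frozen at their
#' last valid position and flagged, never dropped, so released particle
#' count is conserved.
#'
#' @slot lon,lat numeric matrices \code{[particle, stored step]}; \code{NA}
#'   before a particle's release.
#' @slot time numeric stored time points (days, common axis).
#' @slot releases data.frame: \code{id}, \code{region}, \code{cohort},
#'   \code{lon0}, \code{lat0}, \code{t0}.
#' @slot status character per particle: "active", "exited" or "beached".
#' @slot step integration step in days.
#' @export
setClass("Trajectories", representation(
  lon = "matrix", lat = "matrix", time = "numeric",
  releases = "data.frame", status = "character", step = "numeric"))

setValidity("Trajectories", function(object) {
  n <- nrow(object@releases)
  if (nrow(object@lon) != n || nrow(object@lat) != n)
    return("one row of positions per released particle")
  if (length(object@status) != n) return("one status per particle")
  if (!all(object@status %in% c("active", "exited", "beached")))
    return("status must be active/exited/beached")
  if (ncol(object@lon) != length(object@time))
    return("stored columns must match time axis")
  TRUE
})

#' HarmonizedEffort: per-bin-per-year fishing effort in standard units
#'
#' Raw effort records converted to each gear's standard exposure unit
#' (km trawled, km.days, line.days, angler.days) and spread across the
#' 1-degree bins of the gear's area, one row per (gear, year, bin).
#'
#' @slot effort data.frame: \code{gear}, \code{year}, \code{area},
#'   \code{bin_lat}, \code{bin_lon}, \code{effort}, \code{unit}.
#' @export
setClass("HarmonizedEffort", representation(effort = "data.frame"))

setValidity("HarmonizedEffort", function(object) {
  e <- object@effort
  req <- c("gear", "year", "area", "bin_lat", "bin_lon", "effort", "unit")
  if (!all(req %in% names(e)))
    return(paste("effort must have columns", paste(req, collapse = ", ")))
  if (any(e$effort < 0)) return("effort must be non-negative")
  if (anyDuplicated(e[, c("gear", "year", "bin_lat", "bin_lon")]))
    return("one row per (gear, year, bin)")
  TRUE
})

#' AbundanceField: predicted juvenile turtle abundance per bin-year
#'
#' Coastal juvenile abundance by species, year and bin, with the per-age,
#' per-nesting-region components retained. The total in a bin-year is the
#' sum over age classes and regions of hatchling production x coastal
#' recruitment fraction x cumulative oceanic survival.
#'
#' @slot components data.frame: \code{species}, \code{year},
#'   \code{bin_lat}, \code{bin_lon}, \code{region}, \code{age},
#'   \code{abundance}.
#' @slot survivalAnnual annual oceanic survival used for the age scaling.
#' @export
setClass("AbundanceField", representation(
  components = "data.frame", survivalAnnual = "numeric"))

setValidity("AbundanceField", function(object) {
  a <- object@components
  req <- c("species", "year", "bin_lat", "bin_lon", "region", "age", "abundance")
  if (!all(req %in% names(a)))
    return(paste("components must have columns", paste(req, collapse = ", ")))
  if (any(a$abundance < 0)) return("abundance must be non-negative")
  if (object@survivalAnnual <= 0 || object@survivalAnnual > 1)
    return("survivalAnnual must be in (0, 1]")
  TRUE
})

#' BycatchRates: per-bin-year minimum bycatch rates
#'
#' Rates q = T_b / (T_p * F) computed only where bycatch was observed
#' (T_b > 0); records with T_b > 0 but a zero denominator are kept in the
#' \code{excluded} slot for audit, never silently dropped.
#'
#' @slot rates data.frame: \code{species}, \code{gear}, \code{year},
#'   \code{key} (bin or area label), \code{t_b}, \code{t_p}, \code{f},
#'   \code{q}.
#' @slot excluded data.frame of undefined-rate records (same columns,
#'   \code{q} = NA).
#' @slot by granularity of the key: "bin" or "area".
#' @export
setClass("BycatchRates", representation(
  rates = "data.frame", excluded = "data.frame", by = "character"))

setValidity("BycatchRates", function(object) {
  r <- object@rates
  req <- c("species", "gear", "year", "key", "t_b", "t_p", "f", "q")
  if (!all(req %in% names(r)))
    return(paste("rates must have columns", paste(req, collapse = ", ")))
  if (nrow(r) && any(r$q <= 0)) return("rates must be strictly positive")
  if (nrow(r) && any(r$t_b <= 0)) return("rates only defined where t_b > 0")
  if (!object@by %in% c("bin", "area")) return("by must be 'bin' or 'area'")
  TRUE
})

#' RateSummary: geometric-mean bycatch rates with bound brackets
#'
#' Per species-gear geometric mean of all per-bin-year rates, bracketed by
#' the geometric mean of the rates below it (lower bound) and above it
#' (upper bound). A bound whose partition is empty (e.g. a single rate) is
#' undefined and rendered "--".
#'
#' @slot summary data.frame: \code{species}, \code{gear}, \code{n},
#'   \code{gm}, \code{lower}, \code{upper}.
#' @export
setClass("RateSummary", representation(summary = "data.frame"))

setValidity("RateSummary", function(object) {
  s <- object@summary
  req <- c("species", "gear", "n", "gm", "lower", "upper")
  if (!all(req %in% names(s)))
    return(paste("summary must have columns", paste(req, collapse = ", ")))
  ok <- !is.na(s$lower) & !is.na(s$upper)
  if (any(ok & (s$lower > s$gm | s$gm > s$upper)))
    return("bounds must bracket the geometric mean")
  TRUE
})

#' BycatchEstimate: extrapolated annual bycatch totals
#'
#' Annual total bycatch per species and gear, the species-gear geometric
#' mean rate multiplied by the summed annual risk indices, with lower and
#' upper variants from the bound rates.
#'
#' @slot estimates data.frame: \code{species}, \code{gear}, \code{year},
#'   \code{central}, \code{lower}, \code{upper}.
#' @export
setClass("BycatchEstimate", representation(estimates = "data.frame"))

setValidity("BycatchEstimate", function(object) {
  e <- object@estimates
  req <- c("species", "gear", "year", "central", "lower", "upper")
  if (!all(req %in% names(e)))
    return(paste("estimates must have columns", paste(req, collapse = ", ")))
  if (nrow(e) && any(e$central < 0, na.rm = TRUE))
    return("estimates must be non-negative")
  TRUE
})

#' SyntheticWorld: a fully specified synthetic study system
#'
#' Ground-truth description of a synthetic coastal system: grid and
#' coastline, nesting regions with hatchling production, an analytic flow
#' field, fisheries with true catchabilities and effort dynamics. Every
#' pipeline input can be generated from it with a fixed seed, so every
#' downstream stage is testable by recovery of the generating parameters.
#'
#' @slot grid a \linkS4class{BinGrid}.
#' @slot regions data.frame: \code{region}, \code{species}, \code{lon},
#'   \code{lat}, \code{window_start} (day-of-year of first release).
#' @slot hatchlings data.frame: \code{region}, \code{year}, \code{H}.
#' @slot flow list: \code{name} plus flow parameters.
#' @slot species data.frame: \code{species}, \code{max_age} (drift cap, yr).
#' @slot catchability data.frame: \code{species}, \code{gear}, \code{q}.
#' @slot effortSpec named list per gear: base level, annual trend slope,
#'   lognormal noise sd, per-area weights.
#' @slot years integer years covered.
#' @slot survivalAnnual annual oceanic survival.
#' @slot releasesPerDay,windowDays particle release schedule defaults.
#' @slot seed root seed for all generated randomness.
#' @export
setClass("SyntheticWorld", representation(
  grid = "BinGrid", regions = "data.frame", hatchlings = "data.frame",
  flow = "list", species = "data.frame", catchability = "data.frame",
  effortSpec = "list", years = "integer", survivalAnnual = "numeric",
  releasesPerDay = "numeric", windowDays = "numeric", seed = "integer"))

setValidity("SyntheticWorld", function(object) {
  if (any(object@catchability$q < 0)) return("q_true must be >= 0")
  if (any(object@hatchlings$H < 0)) return("hatchling production must be >= 0")
  if (length(object@years) == 0L) return("years must be non-empty")
  g <- object@grid@bins
  inGrid <- object@regions$lon >= min(g$bin_lon) &
    object@regions$lon < max(g$bin_lon) + 1 &
    object@regions$lat >= min(g$bin_lat) &
    object@regions$lat < max(g$bin_lat) + 1
  if (!all(inGrid)) return("grid must cover all release points")
  TRUE
})
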