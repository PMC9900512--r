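#' @include AllClasses.R utils.R
NULL

#' Generate an analytic gridded velocity field
#'
#' Builds a \linkS4class{VelocityField} from one of three analytic flows.
#' Analytic flows are used instead of archived ocean-model output because
#' they admit closed-form reference trajectories for testing the advection
#' kernel; gridded fields from other sources can be read with
#' \code{\link{readVelocityCsv}}.
#'
#' Flows (velocities in degrees/day on the grid coordinates):
#' \describe{
#'   \item{uniform}{constant \code{(u, v)} everywhere.}
#'   \item{solid_rotation}{rigid rotation about \code{(lon0, lat0)} with
#'     angular speed \code{omega} (rad/day): speed at radius r is
#'     \code{omega * r}.}
#'   \item{double_gyre}{the classic two-gyre stream function
#'     \eqn{\psi = A \sin(\pi f(x,t)) \sin(\pi y)} on a 2:1 domain of
#'     width \code{width} degrees anchored at \code{(lon0, lat0)};
#'     \code{eps} modulates the gyre boundary with frequency \code{omega}.
#'     Divergence-free by construction.}
#' }
#'
#' @param flow one of "uniform", "solid_rotation", "double_gyre".
#' @param params named list of flow parameters (see Details).
#' @param lon,lat numeric grid-node coordinates.
#' @param times numeric time points in days.
#' @return a \linkS4class{VelocityField} with units "deg_day".
#' @examples
#' vf <- genVelocityField("uniform", list(u = 0.1, v = 0),
#'                        lon = -98:-80, lat = 23:32, times = 0:10)
#' @export
genVelocityField <- function(flow, params = list(), lon, lat, times) {
  flow <- as.character(flow)
  if (!flow %in% c("uniform", "solid_rotation", "double_gyre"))
    configError("unknown flow name: '", flow, "'")
  if (!all(vapply(params, function(p) all(is.finite(p)), logical(1))))
    configError("flow parameters must be finite")
  nx <- length(lon); ny <- length(lat); nt <- length(times)
  u <- array(0, dim = c(nx, ny, nt))
  v <- array(0, dim = c(nx, ny, nt))
  if (flow == "uniform") {
    u[] <- params$u %||% 0
    v[] <- params$v %||% 0
  } else if (flow == "solid_rotation") {
    omega <- params$omega %||% configError("solid_rotation needs 'omega'")
    lon0 <- params$lon0 %||% mean(lon)
    lat0 <- params$lat0 %||% mean(lat)
    ug <- outer(lon, lat, function(x, y) -omega * (y - lat0))
    vg <- outer(lon, lat, function(x, y) omega * (x - lon0))
    for (k in seq_len(nt)) { u[, , k] <- ug; v[, , k] <- vg }
  } else { # double_gyre
    A <- params$A %||% 0.25
    eps <- params$eps %||% 0
    omega <- params$omega %||% (2 * pi / 10)
    lon0 <- params$lon0 %||% min(lon)
    lat0 <- params$lat0 %||% min(lat)
    width <- params$width %||% 16
    height <- width / 2 # 2:1 aspect of the classic double gyre
    for (k in seq_len(nt)) {
      tk <- times[k]
      a <- eps * sin(omega * tk)
      b <- 1 - 2 * eps * sin(omega * tk)
      xt <- 2 * (lon - lon0) / width          # in [0, 2]
      yt <- (lat - lat0) / height             # in [0, 1]
      f <- a * xt^2 + b * xt
      dfdx <- 2 * a * xt + b
      u[, , k] <- outer(-pi * A / height * sin(pi * f), cos(pi * yt))
      v[, , k] <- outer(pi * A * (2 / width) * cos(pi * f) * dfdx, sin(pi * yt))
    }
  }
  new("VelocityField", lon = as.numeric(lon), lat = as.numeric(lat),
      time = as.numeric(times), u = u, v = v, units = "deg_day")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interpolate a velocity field at particle positions
#'
#' Bilinear in space, linear in time — the standard tracer-advection
#' interpolation. Positions outside the grid return \code{inside = FALSE}
#' with NA velocities; the advection kernel freezes such particles.
#'
#' @param vf a \linkS4class{VelocityField}.
#' @param lon,lat numeric positions (vectorized).
#' @param t scalar or vector time in days.
#' @return list with numeric \code{u}, \code{v} (in the field's units) and
#'   logical \code{inside}.
#' @export
velocityAt <- function(vf, lon, lat, t) {
  nx <- length(vf@lon); ny <- length(vf@lat); nt <- length(vf@time)
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); t <- rep_len(t, n)
  inside <- !is.na(lon) & !is.na(lat) &
    lon >= vf@lon[1] & lon <= vf@lon[nx] &
    lat >= vf@lat[1] & lat <= vf@lat[ny]
  u <- rep(NA_real_, n); v <- rep(NA_real_, n)
  if (!any(inside)) return(list(u = u, v = v, inside = inside))
  x <- lon[inside]; y <- lat[inside]; tq <- t[inside]
  ix <- pmin(pmax(findInterval(x, vf@lon), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(y, vf@lat), 1L), ny - 1L)
  if (nx == 1L) ix <- rep(1L, length(x))
  if (ny == 1L) iy <- rep(1L, length(y))
  fx <- if (nx > 1L) (x - vf@lon[ix]) / (vf@lon[ix + 1L] - vf@lon[ix]) else 0
  fy <- if (ny > 1L) (y - vf@lat[iy]) / (vf@lat[iy + 1L] - vf@lat[iy]) else 0
  ix2 <- if (nx > 1L) ix + 1L else ix
  iy2 <- if (ny > 1L) iy + 1L else iy
  if (nt > 1L) {
    it <- pmin(pmax(findInterval(tq, vf@time), 1L), nt - 1L)
    ft <- (tq - vf@time[it]) / (vf@time[it + 1L] - vf@time[it])
    it2 <- it + 1L
  } else {
    it <- rep(1L, length(tq)); it2 <- it; ft <- 0
  }
  bilin <- function(arr, islice) {
    (1 - fx) * (1 - fy) * arr[cbind(ix, iy, islice)] +
      fx * (1 - fy) * arr[cbind(ix2, iy, islice)] +
      (1 - fx) * fy * arr[cbind(ix, iy2, islice)] +
      fx * fy * arr[cbind(ix2, iy2, islice)]
  }
  u[inside] <- (1 - ft) * bilin(vf@u, it) + ft * bilin(vf@u, it2)
  v[inside] <- (1 - ft) * bilin(vf@v, it) + ft * bilin(vf@v, it2)
  list(u = u, v = v, inside = inside)
}

#' Write / read a velocity field as long-format CSV
#'
#' Columns \code{time}, \code{lat}, \code{lon}, \code{u}, \code{v},
#' \code{units}, one row per grid node and time step.
#'
#' @param vf a \linkS4class{VelocityField}.
#' @param path file path.
#' @return \code{readVelocityCsv} returns a \linkS4class{VelocityField};
#'   \code{writeVelocityCsv} returns \code{path} invisibly.
#' @export
writeVelocityCsv <- function(vf, path) {
  g <- expand.grid(lon = vf@lon, lat = vf@lat, time = vf@time,
                   KEEP.OUT.ATTRS = FALSE)
  g$u <- as.vector(vf@u)
  g$v <- as.vector(vf@v)
  g$units <- vf@units
  utils::write.csv(g[, c("time", "lat", "lon", "u", "v", "units")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVelocityCsv
#' @export
readVelocityCsv <- function(path) {
  g <- utils::read.csv(path)
  needCols(g, c("time", "lat", "lon", "u", "v", "units"), "velocity CSV")
  lon <- sort(unique(g$lon)); lat <- sort(unique(g$lat))
  times <- sort(unique(g$time))
  o <- order(g$time, g$lat, g$lon)
  dims <- c(length(lon), length(lat), length(times))
  if (nrow(g) != prod(dims)) dataError("velocity CSV is not a full grid")
  new("VelocityField", lon = lon, lat = lat, time = times,
      u = array(g$u[o], dims), v = array(g$v[o], dims),
      units = as.character(g$units[1]))
}
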