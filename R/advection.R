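#' @include AllClasses.R velocity.R
NULL

## m/s -> degrees/day at a given latitude (meridian degree ~ 111.32 km)
M_PER_DEG <- 111320

#' Advect particles through a velocity field (RK4)
#'
#' Fourth-order Runge-Kutta time stepping at a fixed step (default half an
#' hour), with bilinear-in-space, linear-in-time velocity interpolation.
#' Particles are released on their own schedule and tracked for
#' \code{duration} days each. A particle that leaves the grid is frozen at
#' its last valid position and flagged "exited"; a particle whose step
#' would land in a land cell is frozen and flagged "beached" (no beaching
#' or resuspension model). Frozen particles are never dropped, so released
#' count is conserved at every step.
#'
#' @param vf a \linkS4class{VelocityField}. Fields in m/s are converted to
#'   degrees/day at the particle latitude (cosine-corrected zonally).
#' @param releases data.frame with columns \code{region}, \code{cohort},
#'   \code{lon0}, \code{lat0}, \code{t0} (release time, days on the
#'   field's time axis); see \code{\link{makeReleaseSchedule}}.
#' @param duration days each particle is tracked after its release.
#' @param stepHours integration step in hours (default 0.5).
#' @param storeEvery store every k-th step (default 1); classification
#'   uses the nearest stored step.
#' @param landMask optional data.frame of land bins (\code{bin_lat},
#'   \code{bin_lon}).
#' @return a \linkS4class{Trajectories}.
#' @export
advectParticles <- function(vf, releases, duration, stepHours = 0.5,
                            storeEvery = 1L, landMask = NULL) {
  needCols(releases, c("region", "cohort", "lon0", "lat0", "t0"), "releases")
  n <- nrow(releases)
  dt <- stepHours / 24
  t0 <- min(releases$t0)
  tEnd <- max(releases$t0) + duration
  if (length(vf@time) > 1L &&
      (t0 < vf@time[1] - 1e-9 || tEnd > vf@time[length(vf@time)] + 1e-9))
    dataError("velocity series does not cover the drift duration (",
              vf@time[1], "-", vf@time[length(vf@time)], " vs needed ",
              t0, "-", tEnd, ")")
  nSteps <- ceiling((tEnd - t0) / dt - 1e-9)
  storeIdx <- unique(c(seq(0L, nSteps, by = as.integer(storeEvery)), nSteps))
  times <- t0 + storeIdx * dt

  landKeys <- if (!is.null(landMask))
    binKey(landMask$bin_lat, landMask$bin_lon) else character(0)

  lonM <- matrix(NA_real_, n, length(storeIdx))
  latM <- matrix(NA_real_, n, length(storeIdx))
  status <- rep("active", n)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  released <- rep(FALSE, n)
  frozen <- rep(FALSE, n)
  deadline <- releases$t0 + duration

  degPerDay <- function(u, v, lat) {
    if (vf@units == "m_s") {
      list(u = u * 86400 / (M_PER_DEG * cos(lat * pi / 180)),
           v = v * 86400 / M_PER_DEG)
    } else list(u = u, v = v)
  }
  ## velocity in deg/day at positions, NA outside grid
  vel <- function(px, py, tt) {
    w <- velocityAt(vf, px, py, tt)
    d <- degPerDay(w$u, w$v, py)
    list(u = d$u, v = d$v, inside = w$inside)
  }

  store <- 1L
  for (s in 0:nSteps) {
    tNow <- t0 + s * dt
    ## release particles whose start time has arrived
    due <- !released & releases$t0 <= tNow + 1e-9
    if (any(due)) {
      x[due] <- releases$lon0[due]
      y[due] <- releases$lat0[due]
      released[due] <- TRUE
    }
    if (store <= length(storeIdx) && s == storeIdx[store]) {
      lonM[, store] <- x
      latM[, store] <- y
      store <- store + 1L
    }
    if (s == nSteps) break
    act <- released & !frozen & tNow < deadline - 1e-9
    if (any(act)) {
      px <- x[act]; py <- y[act]
      k1 <- vel(px, py, tNow)
      k2 <- vel(px + dt / 2 * k1$u, py + dt / 2 * k1$v, tNow + dt / 2)
      k3 <- vel(px + dt / 2 * k2$u, py + dt / 2 * k2$v, tNow + dt / 2)
      k4 <- vel(px + dt * k3$u, py + dt * k3$v, tNow + dt)
      nx <- px + dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
      ny <- py + dt / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
      bad <- !is.finite(nx) | !is.finite(ny) |
        nx < vf@lon[1] | nx > vf@lon[length(vf@lon)] |
        ny < vf@lat[1] | ny > vf@lat[length(vf@lat)]
      onLand <- rep(FALSE, length(nx))
      if (length(landKeys)) {
        ok <- !bad
        onLand[ok] <- binKey(floor(ny[ok]), floor(nx[ok])) %in% landKeys
      }
      idx <- which(act)
      status[idx[bad]] <- "exited"
      status[idx[!bad & onLand]] <- "beached"
      frozen[idx[bad | onLand]] <- TRUE
      move <- !(bad | onLand)
      x[idx[move]] <- nx[move]
      y[idx[move]] <- ny[move]
    }
  }
  rel <- releases
  rel$id <- seq_len(n)
  new("Trajectories", lon = lonM, lat = latM, time = times,
      releases = rel[, c("id", "region", "cohort", "lon0", "lat0", "t0")],
      status = status, step = dt)
}

#' Position of each particle at a given age
#'
#' @param traj a \linkS4class{Trajectories}.
#' @param ageDays age since release in days; the nearest stored step is
#'   used.
#' @return data.frame \code{id}, \code{region}, \code{cohort}, \code{lon},
#'   \code{lat}, \code{age_days} (actual stored age).
#' @export
positionsAtAge <- function(traj, ageDays) {
  rel <- traj@releases
  target <- rel$t0 + ageDays
  maxT <- traj@time[length(traj@time)]
  if (any(target > maxT + traj@step / 2 + 1e-9))
    dataError("requested age ", ageDays,
              " d exceeds the tracked drift duration for some particles")
  cols <- vapply(target, function(tt) which.min(abs(traj@time - tt)), 1L)
  idx <- cbind(rel$id, cols)
  data.frame(id = rel$id, region = rel$region, cohort = rel$cohort,
             lon = traj@lon[idx], lat = traj@lat[idx],
             age_days = traj@time[cols] - rel$t0)
}
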