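test_that("trawl-day conversion uses the published km/day constants", {
  expect_equal(convertTrawlEffort(1, "gulf"), 128.9)
  expect_equal(convertTrawlEffort(1, "atlantic"), 115.6)
  expect_equal(convertTrawlEffort(0, "gulf"), 0)
  ## the constants are consistent with the underlying trawl speeds
  expect_equal(round(knotsToKmPerDay(2.9), 1), 128.9)
  expect_equal(round(knotsToKmPerDay(2.6), 1), 115.6)
  expect_error(convertTrawlEffort(1, "pacific"), "unknown basin")
})

test_that("Atlantic back-extrapolation multiplies Gulf effort by 0.225", {
  gulf <- data.frame(year = 1996:2000, effort = c(100, 200, 0, 50, 80))
  atl <- data.frame(year = 2000, effort = 999)
  out <- extendAtlanticShrimp(gulf, atl, backfillYears = 1996:1999)
  expect_equal(out$effort[out$year == 1996], 22.5)
  expect_equal(out$effort[out$year == 1998], 0)
  expect_equal(out$effort[out$year == 2000], 999) # observed passes through
  expect_true(all(out$backfilled[out$year < 2000]))
  ## a 77.5% mean reduction is exactly the complement of the multiplier
  expect_equal(1 - 0.775, ATLANTIC_SHRIMP_MULTIPLIER)
  expect_error(extendAtlanticShrimp(gulf, atl, backfillYears = 1990),
               "lacks back-fill")
})

test_that("Atlantic spatial partition applies the stated weights literally", {
  out <- partitionAtlanticShrimp(1000)
  expect_equal(out$effort[match(c("EFL", "GA", "SC", "NC"), out$area)],
               c(85, 189, 360, 365))
  ## weights sum to 0.999 and are not renormalized
  expect_equal(sum(out$effort), 999)
  expect_equal(partitionAtlanticShrimp(0)$effort, rep(0, 4))
  obs <- partitionAtlanticShrimp(1000, ATLANTIC_SHRIMP_WEIGHTS_OBSERVER)
  expect_equal(obs$effort[match(c("EFL", "GA", "SC", "NC"), obs$area)],
               c(418, 139, 177, 266))
  expect_error(partitionAtlanticShrimp(10, c(A = -0.1, B = 1.1)),
               "non-negative")
})

test_that("latest-year Gulf partition preserves the prior distribution and total", {
  expect_equal(partitionGulfLatestYear(80, c(A = 10, B = 30)),
               c(A = 20, B = 60))
  expect_equal(unname(partitionGulfLatestYear(100, c(a = 1, b = 1, c = 1, d = 1))),
               rep(25, 4))
  set.seed(11)
  for (i in 1:20) {
    prior <- stats::setNames(runif(5, 0.1, 10), letters[1:5])
    total <- runif(1, 0, 1e4)
    expect_equal(sum(partitionGulfLatestYear(total, prior)), total)
  }
  expect_error(partitionGulfLatestYear(10, c(A = 0, B = 0)), "degenerate")
})

test_that("set-gear and line-gear unit formulas", {
  expect_equal(longlineEffort(10, 1), 2.083)
  expect_equal(round(5 / 24, 4), LONGLINE_SOAK_DAYS)
  expect_equal(longlineEffort(5, 0), 0)
  expect_equal(gillnetEffort(2, 3, 0.5), 3)
  expect_equal(gillnetEffort(0, 10, 2), 0)
  expect_equal(gillnetEffort(7, 2, LONGLINE_SOAK_DAYS), longlineEffort(7, 2))
  expect_equal(hooklineEffort(10, 24), 10)
  expect_equal(hooklineEffort(4, 6), 1)
  expect_equal(hooklineEffort(0, 100), 0)
})

test_that("recreational effort converts trips via state trip durations", {
  expect_equal(recreationalEffort(24, "TX"), 5.6)
  expect_equal(recreationalEffort(24, "NC"), 2.4)
  expect_equal(recreationalEffort(0, "VA"), 0)
  expect_error(recreationalEffort(10, "ZZ"), "unknown state")
})

test_that("all unit conversions are linear and homogeneous", {
  for (c0 in c(0.5, 3, 117.2)) {
    expect_equal(convertTrawlEffort(c0 * 7, "gulf"),
                 c0 * convertTrawlEffort(7, "gulf"))
    expect_equal(longlineEffort(c0 * 2, 5), c0 * longlineEffort(2, 5))
    expect_equal(hooklineEffort(c0 * 3, 12), c0 * hooklineEffort(3, 12))
    expect_equal(recreationalEffort(c0 * 10, "MS"),
                 c0 * recreationalEffort(10, "MS"))
  }
  expect_equal(convertTrawlEffort(0, "atlantic"), 0)
  expect_equal(recreationalEffort(0, "TX"), 0)
})

test_that("rasterization spreads area effort evenly and conserves totals", {
  memb <- data.frame(area = c(rep("TX", 4), "MS"),
                     bin_lat = 28L, bin_lon = c(-97:-94, -90))
  ae <- data.frame(gear = "recreational", year = 2000,
                   area = c("TX", "MS"), effort = c(100, 77),
                   unit = "angler_days")
  h <- rasterizeEffort(ae, memb)
  e <- effortTable(h)
  expect_equal(e$effort[e$area == "TX"], rep(25, 4))
  expect_equal(e$effort[e$area == "MS"], 77) # single-bin area unchanged
  expect_equal(sum(e$effort), 177)
  ## conservation for arbitrary seeded inputs
  set.seed(5)
  ae2 <- data.frame(gear = "g", year = rep(2001:2003, each = 2),
                    area = rep(c("TX", "MS"), 3),
                    effort = runif(6, 0, 1e5), unit = "u")
  expect_equal(sum(effortTable(rasterizeEffort(ae2, memb))$effort),
               sum(ae2$effort))
  expect_error(rasterizeEffort(data.frame(gear = "g", year = 1, area = "FL",
                                          effort = 1, unit = "u"), memb),
               "no bin membership")
})

test_that("harmonized tables round-trip through CSV unchanged", {
  w <- makeSyntheticWorld(seed = 2, years = 1996:1998)
  h <- harmonizeEffort(genEffort(w), areaMembership(w@grid))
  p <- withr::local_tempfile(fileext = ".csv")
  writeEffortCsv(h, p)
  h2 <- readEffortCsv(p)
  expect_equal(effortTable(h2), effortTable(h))
})

test_that("harmonizeEffort applies each gear's formula before rasterizing", {
  memb <- data.frame(area = "MS", bin_lat = 28L, bin_lon = -90L)
  raw <- list(
    shrimp_trawl = data.frame(year = 2000, area = "MS", basin = "gulf",
                              days_trawled = 2),
    hookline = data.frame(year = 2000, area = "MS", n_lines = 4, hours = 6))
  e <- effortTable(harmonizeEffort(raw, memb))
  expect_equal(e$effort[e$gear == "shrimp_trawl"], 2 * 128.9)
  expect_equal(e$effort[e$gear == "hookline"], 1)
  expect_equal(sort(unique(e$unit)), c("km", "line_days"))
})
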