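test_that("release counts multiply out and match schedule enumeration", {
  expect_equal(countReleases(), 21000)
  expect_equal(countReleases(1, 1), 1)
  regions <- data.frame(region = c("a", "b"), lon = c(-96, -90), lat = 25)
  for (k in c(2, 7)) {
    for (nd in c(1, 5)) {
      sched <- makeReleaseSchedule(regions, cohort = 2000, perDay = k,
                                   windowDays = nd)
      expect_equal(nrow(sched[sched$region == "a", ]), countReleases(k, nd))
      expect_equal(sort(unique(sched$t0)), 0:(nd - 1))
    }
  }
})

test_that("coastal fractions are recruit counts over releases", {
  grid <- binGrid(data.frame(bin_lat = 28L, bin_lon = -97:-95,
                             coastal = c(TRUE, TRUE, FALSE), area = "TX"))
  vf <- genVelocityField("uniform", list(u = 0, v = 0),
                         lon = -98:-94, lat = 27:30, times = c(0, 400))
  ## three stationary particles: two in coastal bins, one in the
  ## non-coastal bin
  rel <- data.frame(region = "r1", cohort = 2000,
                    lon0 = c(-96.5, -96.2, -94.5), lat0 = 28.5, t0 = 0)
  traj <- advectParticles(vf, rel, duration = 200, stepHours = 12)
  fr <- classifyCoastalRecruits(traj, grid, ages = 0.5)
  expect_equal(sum(fr$p), 2 / 3)
  expect_equal(fr$p[fr$bin_lon == -97], 2 / 3) # both recruits in one bin
})

test_that("all-offshore trajectories yield no coastal fractions", {
  grid <- binGrid(data.frame(bin_lat = 28L, bin_lon = -97L, coastal = TRUE,
                             area = "TX"))
  vf <- genVelocityField("uniform", list(u = 0, v = 0),
                         lon = -98:-90, lat = 24:30, times = c(0, 400))
  rel <- data.frame(region = "r1", cohort = 2000, lon0 = -92.5, lat0 = 25.5,
                    t0 = 0)
  traj <- advectParticles(vf, rel, duration = 200, stepHours = 12)
  fr <- classifyCoastalRecruits(traj, grid, ages = 0.5)
  expect_equal(nrow(fr), 0)
})

test_that("fractions match a brute-force recount of stored positions", {
  w <- makeSyntheticWorld(seed = 4)
  vf <- genWorldVelocity(w, days = 200)
  rel <- makeReleaseSchedule(w@regions, cohort = 2000, perDay = 3,
                             windowDays = 4)
  traj <- advectParticles(vf, rel, duration = 190, stepHours = 2,
                          storeEvery = 4L)
  fr <- classifyCoastalRecruits(traj, w@grid, ages = 0.5)
  ## independent recount: nearest stored column per particle, floor-bin,
  ## tally against the coastal roster
  cb <- coastalBins(w@grid)
  pos <- positionsAtAge(traj, 0.5 * 365.25)
  for (i in seq_len(nrow(fr))) {
    row <- fr[i, ]
    inBin <- pos$region == row$region &
      floor(pos$lat) == row$bin_lat & floor(pos$lon) == row$bin_lon
    expect_equal(row$p, sum(inBin) / sum(pos$region == row$region))
  }
  tot <- tapply(fr$p, fr$region, sum)
  expect_true(all(tot <= 1 + 1e-12))
})

test_that("age beyond the species drift cap is a contract error", {
  grid <- binGrid(data.frame(bin_lat = 28L, bin_lon = -97L, coastal = TRUE,
                             area = "TX"))
  traj <- new("Trajectories", lon = matrix(-96.5), lat = matrix(28.5),
              time = 0, releases = data.frame(id = 1L, region = "r",
                                              cohort = 2000, lon0 = -96.5,
                                              lat0 = 28.5, t0 = 0),
              status = "active", step = 1 / 48)
  expect_error(classifyCoastalRecruits(traj, grid, ages = 3.5, maxAge = 2.5),
               "drift cap")
})

test_that("daily survival inverts the annual rate", {
  sd <- dailySurvival(0.817)
  expect_equal(sd^365, 0.817)
  expect_equal(sd, 0.99944, tolerance = 1e-5)
  expect_equal(dailySurvival(1), 1)
  expect_equal(sd^182.5, 0.817^0.5)
  expect_equal(round(sd^182.5, 4), 0.9039)
})

test_that("abundance components multiply production, fraction and survival", {
  hat <- data.frame(region = "r1", year = 1999, H = 1000)
  fr <- data.frame(region = "r1", age = 0.5, bin_lat = 28L, bin_lon = -97L,
                   p = 0.5)
  reg <- data.frame(region = "r1", species = "kemps_ridley")
  af <- abundanceField(hat, fr, reg, years = 2000,
                       speciesCaps = c(kemps_ridley = 2.5))
  expect_equal(abundanceComponents(af)$abundance, 1000 * 0.5 * 0.817^0.5)
  expect_equal(round(abundanceComponents(af)$abundance, 1), 451.9)

  hat0 <- hat; hat0$H <- 0
  af0 <- abundanceField(hat0, fr, reg, years = 2000,
                        speciesCaps = c(kemps_ridley = 2.5))
  expect_equal(abundanceGrid(af0)$t_p, 0)
})

test_that("abundance is linear in hatchling production", {
  w <- makeSyntheticWorld(seed = 5, years = 1996:1999)
  a1 <- abundanceGrid(genAbundance(w))
  hat2 <- w@hatchlings; hat2$H <- 2 * hat2$H
  caps <- stats::setNames(w@species$max_age, w@species$species)
  a2 <- abundanceGrid(abundanceField(hat2, syntheticRecruitFractions(w),
                                     w@regions, w@years, caps,
                                     survivalAnnual = w@survivalAnnual))
  expect_equal(a2$t_p, 2 * a1$t_p)
})

test_that("per-age components decrease with age under constant inputs", {
  ages <- c(0.5, 1.5, 2.5, 3.5)
  hat <- data.frame(region = "r1", year = 1996:2000, H = 1000)
  fr <- data.frame(region = "r1", age = ages, bin_lat = 28L, bin_lon = -97L,
                   p = 0.2)
  reg <- data.frame(region = "r1", species = "green")
  af <- abundanceField(hat, fr, reg, years = 2000,
                       speciesCaps = c(green = 3.5))
  comp <- abundanceComponents(af)
  comp <- comp[order(comp$age), ]
  expect_true(all(diff(comp$abundance) < 0))
})

test_that("species drift caps limit the ages contributing", {
  w <- makeSyntheticWorld(seed = 6, years = 1996:1998)
  comp <- abundanceComponents(genAbundance(w))
  expect_lte(max(comp$age[comp$species == "kemps_ridley"]), 2.5)
  expect_equal(max(comp$age[comp$species == "green"]), 3.5)
})

test_that("missing cohort production is an error, not a silent zero", {
  hat <- data.frame(region = "r1", year = 2000, H = 1000) # no 1999 cohort
  fr <- data.frame(region = "r1", age = 0.5, bin_lat = 28L, bin_lon = -97L,
                   p = 0.5)
  reg <- data.frame(region = "r1", species = "kemps_ridley")
  expect_error(abundanceField(hat, fr, reg, years = 2000,
                              speciesCaps = c(kemps_ridley = 2.5)),
               "missing hatchling production")
})

test_that("age composition percentages sum to 100 and match components", {
  w <- makeSyntheticWorld(seed = 8, years = 1996:1999)
  af <- genAbundance(w)
  ac <- ageComposition(af)
  sums <- tapply(ac$percent, list(ac$species, ac$year), sum)
  expect_true(all(abs(sums - 100) < 0.01))
  ## brute-force recount for one species-year
  comp <- abundanceComponents(af)
  one <- comp[comp$species == "green" & comp$year == 1998, ]
  byAge <- tapply(one$abundance, one$age, sum)
  want <- 100 * byAge / sum(byAge)
  got <- ac[ac$species == "green" & ac$year == 1998, ]
  expect_equal(got$percent, as.numeric(want[as.character(got$age)]))
  ## single age class present => 100%
  hat <- data.frame(region = "r1", year = 1999, H = 50)
  fr <- data.frame(region = "r1", age = 0.5, bin_lat = 28L, bin_lon = -97L,
                   p = 0.3)
  reg <- data.frame(region = "r1", species = "kemps_ridley")
  af1 <- abundanceField(hat, fr, reg, 2000, c(kemps_ridley = 2.5))
  expect_equal(ageComposition(af1)$percent, 100)
})
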