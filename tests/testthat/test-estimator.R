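test_that("rates divide observed bycatch by abundance times effort", {
  cell <- oneCell(tb = 1, tp = 1000, f = 1000)
  r <- rateTable(computeRates(cell$bycatch, cell$abundance, cell$effort))
  expect_equal(r$q, 1e-6)
  cell2 <- oneCell(tb = 2, tp = 5e4, f = 4e3)
  r2 <- rateTable(computeRates(cell2$bycatch, cell2$abundance, cell2$effort))
  expect_equal(r2$q, 1e-8)
})

test_that("zero-count locations never enter rate computation", {
  cell <- oneCell(tb = 0)
  r <- computeRates(cell$bycatch, cell$abundance, cell$effort)
  expect_equal(nrow(rateTable(r)), 0)
  expect_equal(nrow(excludedRecords(r)), 0)
})

test_that("observed bycatch with zero T_p*F is excluded and reported", {
  cell <- oneCell(tb = 3, tp = 0)
  r <- computeRates(cell$bycatch, cell$abundance, cell$effort)
  expect_equal(nrow(rateTable(r)), 0)
  excl <- excludedRecords(r)
  expect_equal(nrow(excl), 1)
  expect_equal(excl$t_b, 3)
  expect_true(is.na(excl$q))
})

test_that("deterministic counts reconstruct the generating catchability", {
  ## counts built as round(q_true * T_p * F) >= 1: every computed rate is
  ## within rounding of q_true
  w <- makeSyntheticWorld(seed = 9, years = 1996:1999)
  ab <- genAbundance(w)
  h <- harmonizeEffort(genEffort(w), areaMembership(w@grid))
  lam <- trueBycatchMeans(ab, h, w@catchability)
  lam$count <- round(lam$lambda)
  stopifnot(all(lam$count >= 1))
  r <- rateTable(computeRates(lam, ab, h, by = "bin"))
  m <- merge(r, w@catchability, by.x = c("species", "gear"),
             by.y = c("species", "gear"))
  relErr <- abs(m$q.x - m$q.y) / m$q.y
  roundingBound <- 0.5 / (m$q.y * m$t_p * m$f)
  expect_true(all(relErr <= roundingBound + 1e-12))
})

test_that("geometric-mean summaries bracket correctly", {
  base <- data.frame(species = "s", gear = "g")
  allEq <- cbind(base[rep(1, 3), ], q = 7e-5)
  s <- summaryTable(summarizeRates(allEq))
  expect_equal(s$gm, 7e-5)
  expect_true(is.na(s$lower) && is.na(s$upper)) # all rates equal the GM

  two <- cbind(base[rep(1, 2), ], q = c(1e-6, 1e-8))
  s2 <- summaryTable(summarizeRates(two))
  expect_equal(s2$gm, 1e-7)
  expect_equal(s2$lower, 1e-8)
  expect_equal(s2$upper, 1e-6)

  one <- cbind(base, q = 5e-10)
  f <- formatRateSummary(summarizeRates(one))
  expect_match(f$rate, "\\(--\\)") # singleton renders the "--" convention
})

test_that("geometric mean matches a log-space oracle on seeded rates", {
  set.seed(123)
  q <- rlnorm(50, meanlog = log(1e-7), sdlog = 2)
  df <- data.frame(species = "s", gear = "g", q = q)
  s <- summaryTable(summarizeRates(df))
  oracle <- exp(mean(log(q)))
  expect_equal(s$gm, oracle, tolerance = 1e-12)
  expect_equal(s$lower, exp(mean(log(q[q < oracle]))), tolerance = 1e-12)
  expect_equal(s$upper, exp(mean(log(q[q > oracle]))), tolerance = 1e-12)
  expect_true(s$lower <= s$gm && s$gm <= s$upper)
  ## permutation invariance
  s2 <- summaryTable(summarizeRates(df[sample(50), ]))
  expect_equal(s2$gm, s$gm)
})

test_that("risk indices are abundance times effort", {
  ab <- tinyAbundance(data.frame(year = c(2000, 2000), bin_lat = 28L,
                                 bin_lon = c(-97L, -96L),
                                 abundance = c(10, 0)))
  ef <- tinyEffort(data.frame(year = 2000, bin_lat = 28L,
                              bin_lon = c(-97L, -96L), effort = c(5, 9)))
  rk <- riskIndices(ab, ef)
  expect_equal(sort(rk$risk), c(0, 50))
  mp <- meanRiskMap(rk)
  expect_true(is.na(mp$log10_risk[mp$mean_risk == 0]))
  ## multi-year mean equals a brute-force average
  ab2 <- tinyAbundance(data.frame(year = 2000:2002, bin_lat = 28L,
                                  bin_lon = -97L, abundance = c(10, 20, 40)))
  ef2 <- tinyEffort(data.frame(year = 2000:2002, bin_lat = 28L,
                               bin_lon = -97L, effort = 2))
  mp2 <- meanRiskMap(riskIndices(ab2, ef2))
  expect_equal(mp2$mean_risk, mean(c(20, 40, 80)))
})

test_that("extrapolating over a single observed bin returns T_b exactly", {
  cell <- oneCell(tb = 13, tp = 2345, f = 678)
  rates <- computeRates(cell$bycatch, cell$abundance, cell$effort)
  summ <- summarizeRates(rates)
  rk <- riskIndices(cell$abundance, cell$effort)
  est <- estimateTable(extrapolateBycatch(summ, rk))
  expect_equal(est$central, 13)
})

test_that("annual totals are invariant to rescaling abundance or effort", {
  for (seed in 1:3) {
    w <- makeSyntheticWorld(seed = seed, years = 1996:1999)
    ab <- genAbundance(w)
    h <- harmonizeEffort(genEffort(w), areaMembership(w@grid))
    byc <- genBycatch(ab, h, w@catchability, seed = childSeed(seed, 30))
    run <- function(a, e) {
      rts <- computeRates(byc, a, e, by = "bin")
      estimateTable(extrapolateBycatch(summarizeRates(rts),
                                       riskIndices(a, e, by = "bin")))
    }
    base <- run(ab, h)
    for (c0 in c(0.25, 7)) {
      compScaled <- abundanceComponents(ab)
      compScaled$abundance <- c0 * compScaled$abundance
      abScaled <- new("AbundanceField", components = compScaled,
                      survivalAnnual = ab@survivalAnnual)
      scaled <- run(abScaled, h)
      expect_equal(scaled$central, base$central)

      efScaled <- effortTable(h)
      efScaled$effort <- c0 * efScaled$effort
      scaledF <- run(ab, new("HarmonizedEffort", effort = efScaled))
      expect_equal(scaledF$central, base$central)
    }
  }
})

test_that("annual geometric means pool years, excluding zero years", {
  est <- new("BycatchEstimate", estimates = data.frame(
    species = "s", gear = "g", year = 2000:2004,
    central = c(100, 100, 100, 100, 100), lower = NA_real_,
    upper = NA_real_))
  expect_equal(annualSummary(est)$gm_annual, 100)
  est2 <- new("BycatchEstimate", estimates = data.frame(
    species = "s", gear = "g", year = 2000:2001, central = c(10, 1000),
    lower = NA_real_, upper = NA_real_))
  expect_equal(annualSummary(est2)$gm_annual, 100)
  ## a zero year is excluded, not propagated as zero
  est3 <- new("BycatchEstimate", estimates = data.frame(
    species = "s", gear = "g", year = 2000:2002, central = c(10, 0, 1000),
    lower = NA_real_, upper = NA_real_))
  a3 <- annualSummary(est3)
  expect_equal(a3$gm_annual, 100)
  expect_equal(a3$n_years, 2)
  ## log-space oracle on a seeded series
  set.seed(77)
  b <- rlnorm(15, log(500), 1)
  est4 <- new("BycatchEstimate", estimates = data.frame(
    species = "s", gear = "g", year = seq_along(b) + 1995, central = b,
    lower = NA_real_, upper = NA_real_))
  expect_equal(annualSummary(est4)$gm_annual, exp(mean(log(b))),
               tolerance = 1e-12)
})

test_that("percent of population divides summed bycatch by total abundance", {
  ab <- tinyAbundance(data.frame(year = 2000, bin_lat = 28L, bin_lon = -97L,
                                 abundance = 1000))
  est <- new("BycatchEstimate", estimates = data.frame(
    species = "kemps_ridley", gear = c("g1", "g2"), year = 2000,
    central = c(3, 2), lower = NA_real_, upper = NA_real_))
  p <- percentOfPopulation(est, ab)
  expect_equal(p$percent, 0.5)
  est0 <- new("BycatchEstimate", estimates = data.frame(
    species = "kemps_ridley", gear = "g1", year = 2000, central = 0,
    lower = NA_real_, upper = NA_real_))
  expect_equal(percentOfPopulation(est0, ab)$percent, 0)
})

test_that("trend tests match the textbook Pearson formula", {
  tt <- trendTest(2000:2009, 3 * (2000:2009) + 7)
  expect_equal(tt$r, 1)
  expect_true(is.na(trendTest(2000:2009, rep(5, 10))$r))
  set.seed(42)
  y <- rnorm(22)
  yr <- 1996:2017
  tt2 <- trendTest(yr, y)
  r <- sum((yr - mean(yr)) * (y - mean(y))) /
    sqrt(sum((yr - mean(yr))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((22 - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = 20)
  expect_equal(tt2$r, r, tolerance = 1e-12)
  expect_equal(tt2$p, p, tolerance = 1e-12)
  expect_equal(tt2$n, 22)
})

test_that("rate-trend check regresses log rates on year", {
  const <- data.frame(species = "s", gear = "g", year = 2000:2009, q = 1e-6)
  expect_equal(rateTrendCheck(const)$r_squared, 0)
  expo <- data.frame(species = "s", gear = "g", year = 2000:2009,
                     q = 1e-6 * exp(0.2 * (0:9)))
  expect_equal(rateTrendCheck(expo)$r_squared, 1)
  set.seed(13)
  noisy <- data.frame(species = "s", gear = "g", year = 2000:2019,
                      q = rlnorm(20, log(1e-7), 0.8))
  got <- rateTrendCheck(noisy)
  ## closed-form OLS oracle on the log scale
  x <- noisy$year; y <- log(noisy$q)
  r2 <- cor(x, y)^2
  expect_equal(got$r_squared, r2, tolerance = 1e-12)
  expect_equal(got$n, 20)
})

test_that("conditioning on observed bycatch inflates small-lambda rates", {
  ## with tiny Poisson means, only lucky cells are observed, so the GM of
  ## computed rates sits above the generating catchability on average
  set.seed(2024)
  qTrue <- 1e-6
  nRep <- 200
  gmHats <- replicate(nRep, {
    tp <- runif(40, 50, 150); f <- runif(40, 20, 80)
    lam <- qTrue * tp * f # mean ~ 0.005: deeply sparse
    n <- rpois(40, lam)
    keep <- n > 0
    if (!any(keep)) NA_real_ else exp(mean(log(n[keep] / (tp[keep] * f[keep]))))
  })
  expect_gt(mean(gmHats, na.rm = TRUE), qTrue)
})

test_that("arithmetic-mean rates upper-bound geometric-mean totals", {
  w <- makeSyntheticWorld(seed = 10, years = 1996:1999)
  ab <- genAbundance(w)
  h <- harmonizeEffort(genEffort(w), areaMembership(w@grid))
  byc <- genBycatch(ab, h, w@catchability, seed = 55)
  rts <- computeRates(byc, ab, h, by = "bin")
  rk <- riskIndices(ab, h, by = "bin")
  gmEst <- estimateTable(extrapolateBycatch(summarizeRates(rts), rk))
  r <- rateTable(rts)
  am <- aggregate(list(am = r$q), by = list(species = r$species,
                                            gear = r$gear), FUN = mean)
  annRisk <- aggregate(list(sr = rk$risk),
                       by = list(species = rk$species, gear = rk$gear,
                                 year = rk$year), FUN = sum)
  m <- merge(merge(annRisk, am), gmEst, by = c("species", "gear", "year"))
  expect_true(all(m$am * m$sr >= m$central - 1e-9))
})
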