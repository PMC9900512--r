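#' @include AllClasses.R recruitment.R effort.R utils.R
NULL

## build the (key, t_p, f) alignment at bin or area granularity
alignRiskBase <- function(abundance, effort, by = c("bin", "area")) {
  by <- match.arg(by)
  tp <- abundanceGrid(abundance)
  ef <- effortTable(effort)
  ef <- merge(ef, data.frame(species = unique(tp$species)))
  m <- merge(ef, tp, by = c("species", "year", "bin_lat", "bin_lon"),
             all.x = TRUE)
  m$t_p[is.na(m$t_p)] <- 0
  if (by == "bin") {
    m$key <- binKey(m$bin_lat, m$bin_lon)
    m[, c("species", "gear", "year", "key", "t_p", "effort")]
  } else {
    a <- stats::aggregate(
      cbind(t_p = m$t_p, effort = m$effort) ~ species + gear + year + area,
      data = m, FUN = sum)
    a$key <- a$area
    a[, c("species", "gear", "year", "key", "t_p", "effort")]
  }
}

#' Compute per-bin-year minimum bycatch rates
#'
#' For every record with observed bycatch (T_b > 0), the rate is
#' \code{q = T_b / (T_p * F)} where T_p is the modelled abundance and F
#' the harmonized effort at the same key. Locations without observed
#' bycatch are not considered. Records with T_b > 0 but T_p or F zero
#' cannot yield a rate; they are reported in the \code{excluded} slot and
#' never enter summaries.
#'
#' Matching granularity follows how the records were aggregated:
#' \code{by = "bin"} for commercial records keyed to 1-degree bins,
#' \code{by = "area"} for records aggregated by state/subregion (the
#' recreational convention), in which case T_p and F are summed over the
#' area's bins before division.
#'
#' @param bycatch data.frame: \code{species}, \code{gear}, \code{year},
#'   \code{count}, plus \code{bin_lat}/\code{bin_lon} (by = "bin") or
#'   \code{area} (by = "area").
#' @param abundance an \linkS4class{AbundanceField}.
#' @param effort a \linkS4class{HarmonizedEffort}.
#' @param by "bin" or "area".
#' @return a \linkS4class{BycatchRates}.
#' @export
computeRates <- function(bycatch, abundance, effort, by = c("bin", "area")) {
  by <- match.arg(by)
  needCols(bycatch, c("species", "gear", "year", "count"), "bycatch records")
  if (any(bycatch$count < 0)) dataError("bycatch counts must be >= 0")
  obs <- bycatch[bycatch$count > 0, , drop = FALSE]
  if (by == "bin") {
    needCols(obs, c("bin_lat", "bin_lon"), "bycatch records")
    obs$key <- binKey(obs$bin_lat, obs$bin_lon)
  } else {
    needCols(obs, c("area"), "bycatch records")
    obs$key <- obs$area
  }
  ## aggregate multiple records at the same key-year
  if (nrow(obs)) {
    obs <- stats::aggregate(
      list(t_b = obs$count),
      by = list(species = obs$species, gear = obs$gear, year = obs$year,
                key = obs$key), FUN = sum)
  } else {
    obs <- data.frame(species = character(), gear = character(),
                      year = integer(), key = character(), t_b = numeric())
  }
  base <- alignRiskBase(abundance, effort, by)
  m <- merge(obs, base, by = c("species", "gear", "year", "key"), all.x = TRUE)
  m$t_p[is.na(m$t_p)] <- 0
  m$effort[is.na(m$effort)] <- 0
  m$q <- ifelse(m$t_p > 0 & m$effort > 0, m$t_b / (m$t_p * m$effort), NA_real_)
  keep <- !is.na(m$q)
  rates <- m[keep, , drop = FALSE]
  excl <- m[!keep, , drop = FALSE]
  cols <- c("species", "gear", "year", "key", "t_b", "t_p", "f", "q")
  names(rates)[names(rates) == "effort"] <- "f"
  names(excl)[names(excl) == "effort"] <- "f"
  rates <- rates[order(rates$species, rates$gear, rates$year, rates$key), cols]
  excl <- excl[, cols]
  rownames(rates) <- rownames(excl) <- NULL
  new("BycatchRates", rates = rates, excluded = excl, by = by)
}

#' Geometric-mean rate summary with lower/upper bound brackets
#'
#' Per species-gear: the geometric mean GM of all rates; the lower bound
#' is the geometric mean of the rates strictly below GM and the upper
#' bound the geometric mean of those strictly above (rates exactly equal
#' to GM enter neither set). An empty partition leaves that bound
#' undefined (rendered "--"); a species-gear with no rates is dropped.
#'
#' @param rates a \linkS4class{BycatchRates} or a data.frame with columns
#'   \code{species}, \code{gear}, \code{q}.
#' @return a \linkS4class{RateSummary}.
#' @export
summarizeRates <- function(rates) {
  r <- if (is(rates, "BycatchRates")) rateTable(rates) else rates
  needCols(r, c("species", "gear", "q"), "rates")
  if (nrow(r) == 0L)
    return(new("RateSummary", summary = data.frame(
      species = character(), gear = character(), n = integer(),
      gm = numeric(), lower = numeric(), upper = numeric())))
  grp <- split(r, list(r$species, r$gear), drop = TRUE)
  rows <- lapply(grp, function(g) {
    q <- g$q
    gm <- geomMean(q)
    ## "equal to the GM" is judged at 1e-12 relative: exponentiating the
    ## mean log perturbs an exact tie by a few ulps of rounding error
    eps <- 1e-12
    lo <- q[q < gm * (1 - eps)]; hi <- q[q > gm * (1 + eps)]
    data.frame(species = g$species[1], gear = g$gear[1], n = length(q),
               gm = gm,
               lower = if (length(lo)) geomMean(lo) else NA_real_,
               upper = if (length(hi)) geomMean(hi) else NA_real_)
  })
  s <- do.call(rbind, rows)
  s <- s[order(s$species, s$gear), ]
  rownames(s) <- NULL
  new("RateSummary", summary = s)
}

#' Render a rate summary in the published table layout
#'
#' One row per species-gear with the geometric mean and the bound bracket
#' in parentheses; an undefined bracket (both bounds empty, e.g. a single
#' computed rate) renders as "(--)".
#'
#' @param x a \linkS4class{RateSummary}.
#' @param digits significant digits (default 1, matching the published
#'   one-significant-figure convention).
#' @return data.frame \code{species}, \code{gear}, \code{rate} (character).
#' @export
formatRateSummary <- function(x, digits = 1) {
  s <- summaryTable(x)
  fmt <- function(v) ifelse(is.na(v), "--", signif(v, digits))
  bracket <- ifelse(is.na(s$lower) & is.na(s$upper), "(--)",
                    paste0("(", fmt(s$lower), "-", fmt(s$upper), ")"))
  data.frame(species = s$species, gear = s$gear,
             rate = paste(signif(s$gm, digits), bracket))
}

#' Risk indices: modelled abundance times fishing effort
#'
#' R = T_p x F per species, gear, year and bin (or area) — the exposure
#' base over which geometric-mean rates are extrapolated, and the mapped
#' overlap index (multi-year mean on a log10 scale; log10 of zero is
#' rendered missing).
#'
#' @param abundance an \linkS4class{AbundanceField}.
#' @param effort a \linkS4class{HarmonizedEffort}.
#' @param by "bin" or "area" granularity.
#' @return data.frame \code{species}, \code{gear}, \code{year},
#'   \code{key}, \code{t_p}, \code{f}, \code{risk}.
#' @export
riskIndices <- function(abundance, effort, by = c("bin", "area")) {
  base <- alignRiskBase(abundance, effort, match.arg(by))
  base$risk <- base$t_p * base$effort
  names(base)[names(base) == "effort"] <- "f"
  base
}

#' Multi-year mean risk for mapping
#'
#' @param risk output of \code{\link{riskIndices}}.
#' @return data.frame \code{species}, \code{gear}, \code{key},
#'   \code{mean_risk}, \code{log10_risk} (NA where the mean is 0).
#' @export
meanRiskMap <- function(risk) {
  m <- stats::aggregate(list(mean_risk = risk$risk),
                        by = list(species = risk$species, gear = risk$gear,
                                  key = risk$key), FUN = mean)
  m$log10_risk <- ifelse(m$mean_risk > 0, log10(m$mean_risk), NA_real_)
  m
}

#' Extrapolate annual total bycatch over summed risk indices
#'
#' B_y = GM x sum over bins of R(bin, y) per species-gear, with lower and
#' upper variants using the bound rates. Species-gears without a rate
#' summary are dropped (no rates means no extrapolation, matching the
#' published treatment of gears with zero observed bycatch).
#'
#' @param summary a \linkS4class{RateSummary}.
#' @param risk output of \code{\link{riskIndices}}.
#' @return a \linkS4class{BycatchEstimate}.
#' @export
extrapolateBycatch <- function(summary, risk) {
  s <- summaryTable(summary)
  annRisk <- stats::aggregate(list(sum_risk = risk$risk),
                              by = list(species = risk$species,
                                        gear = risk$gear, year = risk$year),
                              FUN = sum)
  m <- merge(annRisk, s, by = c("species", "gear"))
  est <- data.frame(species = m$species, gear = m$gear, year = m$year,
                    central = m$gm * m$sum_risk,
                    lower = m$lower * m$sum_risk,
                    upper = m$upper * m$sum_risk)
  est <- est[order(est$species, est$gear, est$year), ]
  rownames(est) <- NULL
  new("BycatchEstimate", estimates = est)
}

#' Geometric mean of annual bycatch totals
#'
#' Per species-gear, the geometric mean over years of the annual totals.
#' Years with a zero total (no effort, or an undefined rate) are excluded
#' rather than mapped to zero: a geometric mean over a set containing
#' zero is degenerate, and gears that never catch are reported
#' categorically instead.
#'
#' @param estimates a \linkS4class{BycatchEstimate}.
#' @return data.frame \code{species}, \code{gear}, \code{n_years},
#'   \code{gm_annual}.
#' @export
annualSummary <- function(estimates) {
  e <- estimateTable(estimates)
  e <- e[!is.na(e$central) & e$central > 0, , drop = FALSE]
  if (nrow(e) == 0L)
    return(data.frame(species = character(), gear = character(),
                      n_years = integer(), gm_annual = numeric()))
  grp <- split(e, list(e$species, e$gear), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(species = g$species[1], gear = g$gear[1],
               n_years = nrow(g), gm_annual = geomMean(g$central))
  }))
  out <- out[order(out$species, out$gear), ]
  rownames(out) <- NULL
  out
}

#' Bycatch as percent of the modelled population
#'
#' P_y = 100 x (sum over gears of B_{g,y}) / N_y, where N_y is the total
#' modelled coastal abundance of the species in year y.
#'
#' @param estimates a \linkS4class{BycatchEstimate}.
#' @param abundance an \linkS4class{AbundanceField}.
#' @return data.frame \code{species}, \code{year}, \code{bycatch},
#'   \code{population}, \code{percent}.
#' @export
percentOfPopulation <- function(estimates, abundance) {
  e <- estimateTable(estimates)
  tot <- stats::aggregate(list(bycatch = e$central),
                          by = list(species = e$species, year = e$year),
                          FUN = sum)
  tp <- abundanceGrid(abundance)
  pop <- stats::aggregate(list(population = tp$t_p),
                          by = list(species = tp$species, year = tp$year),
                          FUN = sum)
  m <- merge(tot, pop, by = c("species", "year"))
  m$percent <- ifelse(m$population > 0, 100 * m$bycatch / m$population,
                      NA_real_)
  m[order(m$species, m$year), ]
}

#' Pearson trend test of an annual series
#'
#' Pearson correlation of the series against year with a two-sided
#' t-distribution p-value (n - 2 df), via \code{stats::cor.test}. A
#' zero-variance series has no defined correlation and is reported as NA.
#'
#' @param years numeric years.
#' @param values numeric series.
#' @return list \code{r}, \code{p}, \code{n}.
#' @export
trendTest <- function(years, values) {
  ok <- is.finite(years) & is.finite(values)
  years <- years[ok]; values <- values[ok]
  n <- length(values)
  if (n < 3L || stats::sd(values) == 0 || stats::sd(years) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(years, values, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Temporal-trend check of bycatch rates
#'
#' Ordinary least squares of log(q) on year (log scale, consistent with
#' geometric-mean aggregation of the rates); reports R-squared, the
#' slope's two-sided p-value and n. Used to justify pooling rates across
#' years into a single geometric mean.
#'
#' @param rates a \linkS4class{BycatchRates} or data.frame with \code{q},
#'   \code{year}.
#' @param scale "log" (default) or "identity".
#' @return data.frame per species-gear: \code{species}, \code{gear},
#'   \code{r_squared}, \code{p}, \code{n}, \code{scale}.
#' @export
rateTrendCheck <- function(rates, scale = c("log", "identity")) {
  scale <- match.arg(scale)
  r <- if (is(rates, "BycatchRates")) rateTable(rates) else rates
  needCols(r, c("species", "gear", "year", "q"), "rates")
  grp <- split(r, list(r$species, r$gear), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    y <- if (scale == "log") log(g$q) else g$q
    n <- nrow(g)
    if (n < 3L || stats::sd(y) == 0 || stats::sd(g$year) == 0)
      return(data.frame(species = g$species[1], gear = g$gear[1],
                        r_squared = if (n >= 2L && stats::sd(y) == 0) 0 else NA_real_,
                        p = NA_real_, n = n, scale = scale))
    fit <- summary(stats::lm(y ~ year, data = g))
    data.frame(species = g$species[1], gear = g$gear[1],
               r_squared = fit$r.squared,
               p = stats::coef(fit)["year", "Pr(>|t|)"], n = n, scale = scale)
  }))
  rownames(out) <- NULL
  out
}
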