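#' @include utils.R
NULL

#' Assemble an observer-program comparison series
#'
#' Sums published observer-based bycatch estimates (median and 95\% CI)
#' over basins and net classes (standard + try nets) into a single
#' per-year comparison total. A basin-year missing at the end of a
#' basin's series is filled with the mean of that basin's previous three
#' years (applied to the median and both CI bounds alike) before summing;
#' fewer than three prior years is a missing-data error.
#'
#' @param series data.frame: \code{species}, \code{basin}, \code{net}
#'   ("standard" or "try"), \code{year}, \code{median}, \code{ci_low},
#'   \code{ci_high}.
#' @param years years the assembled series must cover (default: all years
#'   present in any basin).
#' @return data.frame per species-year: \code{species}, \code{year},
#'   \code{median}, \code{ci_low}, \code{ci_high}, \code{filled}
#'   (comma-separated basins that needed the fill rule, "" if none).
#' @export
assembleObserverSeries <- function(series, years = NULL) {
  needCols(series, c("species", "basin", "net", "year", "median",
                     "ci_low", "ci_high"), "observer series")
  if (any(series$ci_low > series$median | series$median > series$ci_high))
    dataError("CI bounds must bracket the median")
  if (is.null(years)) years <- sort(unique(series$year))
  ## collapse net classes within basin-year first
  bas <- stats::aggregate(
    cbind(median = series$median, ci_low = series$ci_low,
          ci_high = series$ci_high) ~ species + basin + year,
    data = series, FUN = sum)
  out <- list()
  for (sp in unique(bas$species)) {
    b <- bas[bas$species == sp, ]
    for (y in years) {
      have <- b[b$year == y, ]
      filled <- character(0)
      for (basin in unique(b$basin)) {
        if (!basin %in% have$basin) {
          prior <- b[b$basin == basin & b$year %in% (y - 3):(y - 1), ]
          if (nrow(prior) < 3L)
            dataError("basin '", basin, "' missing year ", y,
                      " with fewer than three prior years to fill from")
          have <- rbind(have, data.frame(
            species = sp, basin = basin, year = y,
            median = mean(prior$median), ci_low = mean(prior$ci_low),
            ci_high = mean(prior$ci_high)))
          filled <- c(filled, basin)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        species = sp, year = y,
        median = sum(have$median), ci_low = sum(have$ci_low),
        ci_high = sum(have$ci_high),
        filled = paste(filled, collapse = ","))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
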