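## Shared fixture builders. Everything is constructed in code; nothing is
## read from disk except files the tests themselves write to tempdirs.

## a minimal abundance field: one species/region/age, explicit bins
tinyAbundance <- function(df, survival = 0.817) {
  defaults <- data.frame(species = "kemps_ridley", region = "r1", age = 0.5)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  new("AbundanceField",
      components = df[, c("species", "year", "bin_lat", "bin_lon",
                          "region", "age", "abundance")],
      survivalAnnual = survival)
}

## a minimal harmonized effort table
tinyEffort <- function(df, gear = "gillnet", unit = "km_days") {
  if (!"gear" %in% names(df)) df$gear <- gear
  if (!"unit" %in% names(df)) df$unit <- unit
  if (!"area" %in% names(df)) df$area <- "A1"
  new("HarmonizedEffort",
      effort = df[, c("gear", "year", "area", "bin_lat", "bin_lon",
                      "effort", "unit")])
}

## single-cell world pieces: T_p and F in one bin-year, for identities
oneCell <- function(tb = 4, tp = 1000, f = 1000, year = 2000,
                    lat = 28L, lon = -97L, gear = "gillnet") {
  list(
    abundance = tinyAbundance(data.frame(
      year = year, bin_lat = lat, bin_lon = lon, abundance = tp)),
    effort = tinyEffort(data.frame(
      year = year, bin_lat = lat, bin_lon = lon, effort = f), gear = gear),
    bycatch = data.frame(species = "kemps_ridley", gear = gear, year = year,
                         bin_lat = lat, bin_lon = lon, count = tb))
}

## analytic circular-orbit endpoint for solid-body rotation
orbitPosition <- function(lon0, lat0, center, omega, t) {
  dx <- lon0 - center[1]; dy <- lat0 - center[2]
  th <- omega * t
  c(center[1] + dx * cos(th) - dy * sin(th),
    center[2] + dx * sin(th) + dy * cos(th))
}
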