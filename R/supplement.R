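#' @include utils.R
NULL

#' Parse supplement-style bin column headers
#'
#' In the supplementary risk tables, 1-degree bin columns are headed by a
#' four-digit code: the first two digits give the bin-center latitude
#' (degrees N) and the last two the bin-center longitude (degrees W), e.g.
#' "2897" is the bin centred at 28.5 N, 97.5 W (floor ids 28, -97 under
#' the half-open convention, since centres sit at x.5).
#'
#' @param header character vector of column headers; non-bin headers
#'   return NA rows.
#' @return data.frame \code{header}, \code{bin_lat}, \code{bin_lon}.
#' @export
parseBinHeader <- function(header) {
  code <- sub("^[Xx]", "", as.character(header)) # R prepends X to numerics
  isBin <- grepl("^[0-9]{4}$", code)
  lat <- lon <- rep(NA_integer_, length(code))
  lat[isBin] <- as.integer(substr(code[isBin], 1, 2))
  lon[isBin] <- -as.integer(substr(code[isBin], 3, 4))
  data.frame(header = as.character(header), bin_lat = lat, bin_lon = lon)
}

#' Read a supplement-layout risk or bycatch sheet from CSV
#'
#' Reads one sheet of the supplementary-spreadsheet layout serialized as
#' CSV. Risk sheets ("Shrimp_Risk", "Rec_Risk", "BLL_Risk",
#' "Gillnet_Risk", "H&L_Risk") are wide: a \code{species} column, a
#' \code{year} column, then one column per spatial unit — either a named
#' area/zone (e.g. "GOM_Area_4", "TX", "GOM_Z18") or a four-digit bin
#' code parsed by \code{\link{parseBinHeader}}. The "Bycatch" sheet is
#' long with columns \code{species}, \code{gear}, \code{year},
#' \code{location}, \code{count}.
#'
#' @param path CSV file path.
#' @param sheet "risk" (wide layout) or "bycatch" (long layout).
#' @return for "risk": long data.frame \code{species}, \code{year},
#'   \code{unit}, \code{bin_lat}, \code{bin_lon} (NA for named units),
#'   \code{risk}; for "bycatch": the long table as read.
#' @export
readSupplementSheet <- function(path, sheet = c("risk", "bycatch")) {
  sheet <- match.arg(sheet)
  df <- utils::read.csv(path, check.names = TRUE)
  if (sheet == "bycatch") {
    needCols(df, c("species", "gear", "year", "location", "count"),
             "bycatch sheet")
    return(df)
  }
  needCols(df, c("species", "year"), "risk sheet")
  unitCols <- setdiff(names(df), c("species", "year"))
  if (!length(unitCols)) dataError("risk sheet has no spatial-unit columns")
  hdr <- parseBinHeader(unitCols)
  out <- do.call(rbind, lapply(seq_along(unitCols), function(j) {
    data.frame(species = df$species, year = df$year,
               unit = sub("^[Xx](?=[0-9]{4}$)", "", unitCols[j], perl = TRUE),
               bin_lat = hdr$bin_lat[j], bin_lon = hdr$bin_lon[j],
               risk = as.numeric(df[[unitCols[j]]]))
  }))
  rownames(out) <- NULL
  out
}

#' Read a directory of supplement-layout sheets
#'
#' Expects files named \code{Bycatch.csv}, \code{Shrimp_Risk.csv},
#' \code{Rec_Risk.csv}, \code{BLL_Risk.csv}, \code{Gillnet_Risk.csv},
#' \code{HL_Risk.csv} (any subset); risk sheets are tagged with the gear
#' they describe.
#'
#' @param dir directory containing the sheet CSVs.
#' @return list with \code{bycatch} (long table or NULL) and \code{risk}
#'   (long table with a \code{gear} column).
#' @export
readSupplementDir <- function(dir) {
  gearOf <- c(Shrimp_Risk = "shrimp_trawl", Rec_Risk = "recreational",
              BLL_Risk = "longline", Gillnet_Risk = "gillnet",
              HL_Risk = "hookline")
  risk <- list()
  for (nm in names(gearOf)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) {
      r <- readSupplementSheet(f, "risk")
      r$gear <- unname(gearOf[nm])
      risk[[nm]] <- r
    }
  }
  bPath <- file.path(dir, "Bycatch.csv")
  list(bycatch = if (file.exists(bPath))
         readSupplementSheet(bPath, "bycatch") else NULL,
       risk = if (length(risk)) do.call(rbind, risk) else NULL)
}
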