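#' @include AllClasses.R
NULL

#' Construct a 1-degree bin grid
#'
#' @param bins data.frame with integer \code{bin_lat}, \code{bin_lon},
#'   logical \code{coastal} and character \code{area} (NA allowed).
#' @return a \linkS4class{BinGrid}.
#' @examples
#' g <- binGrid(data.frame(bin_lat = 28, bin_lon = -97:-95,
#'                         coastal = TRUE, area = "TX"))
#' @export
binGrid <- function(bins) {
  bins$bin_lat <- as.integer(bins$bin_lat)
  bins$bin_lon <- as.integer(bins$bin_lon)
  bins$area <- as.character(bins$area)
  new("BinGrid", bins = bins[, c("bin_lat", "bin_lon", "coastal", "area")])
}

#' Assign points to 1-degree bins
#'
#' Bins are half-open \code{[lat, lat+1) x [lon, lon+1)} so boundary points
#' are assigned unambiguously: the bin id is the integer floor.
#'
#' @param lat,lon numeric coordinates.
#' @return data.frame with \code{bin_lat}, \code{bin_lon}.
#' @export
latLonToBin <- function(lat, lon) {
  data.frame(bin_lat = as.integer(floor(lat)), bin_lon = as.integer(floor(lon)))
}

#' Area-to-bin membership table
#'
#' @param x a \linkS4class{BinGrid}.
#' @return data.frame \code{area}, \code{bin_lat}, \code{bin_lon}, coastal
#'   bins only, one row per member bin.
#' @export
areaMembership <- function(x) {
  b <- bins(x)
  b <- b[b$coastal & !is.na(b$area), c("area", "bin_lat", "bin_lon")]
  rownames(b) <- NULL
  b
}

#' Coastal bins of a grid
#'
#' @param x a \linkS4class{BinGrid}.
#' @return the coastal subset of \code{bins(x)}.
#' @export
coastalBins <- function(x) {
  b <- bins(x)
  b[b$coastal, , drop = FALSE]
}
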