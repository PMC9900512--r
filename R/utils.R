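#' Geometric mean
#'
#' Computed in log space, \code{exp(mean(log(x)))}. All values must be
#' strictly positive; the geometric mean of a set containing zero is
#' degenerate and refused.
#'
#' @param x numeric vector of positive values.
#' @param na.rm drop \code{NA}s before averaging.
#' @return the geometric mean, a single numeric.
#' @export
geomMean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) stop("geomMean() requires strictly positive values")
  exp(mean(log(x)))
}

#' Derive a child seed from a root seed
#'
#' All randomness in the package fans out from a single root seed; each
#' component draws from its own child stream so components can be
#' regenerated independently. The derivation is a fixed affine map modulo
#' 2^31 - 1 (keeps seeds in 32-bit integer range).
#'
#' @param seed root integer seed.
#' @param k integer index of the child stream (>= 1).
#' @return an integer seed.
#' @export
childSeed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  as.integer((as.double(seed) %% 2147483647 * 1000003 + 7919 * k) %% 2147483647)
}

## internal: stop with a class so callers can distinguish config/data errors
configError <- function(...) {
  stop(errorCondition(paste0(...), class = c("turtleRisk_config_error", "error")))
}
dataError <- function(...) {
  stop(errorCondition(paste0(...), class = c("turtleRisk_data_error", "error")))
}

## internal: check a data.frame has the named columns
needCols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    dataError(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

## internal: paste bin key
binKey <- function(lat, lon) paste(lat, lon, sep = ":")
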