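#' @include AllClasses.R
NULL

#' Accessors for turtleRisk containers
#'
#' Slot access goes through these accessors rather than \code{@}.
#'
#' @param x a turtleRisk S4 object.
#' @return the underlying data.frame (or vector) for the requested piece.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))
#' @rdname accessors
#' @export
setGeneric("effortTable", function(x) standardGeneric("effortTable"))
#' @rdname accessors
#' @export
setGeneric("abundanceComponents", function(x) standardGeneric("abundanceComponents"))
#' @rdname accessors
#' @export
setGeneric("abundanceGrid", function(x, ...) standardGeneric("abundanceGrid"))
#' @rdname accessors
#' @export
setGeneric("rateTable", function(x) standardGeneric("rateTable"))
#' @rdname accessors
#' @export
setGeneric("excludedRecords", function(x) standardGeneric("excludedRecords"))
#' @rdname accessors
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))
#' @rdname accessors
#' @export
setGeneric("estimateTable", function(x) standardGeneric("estimateTable"))

#' @rdname accessors
#' @export
setMethod("bins", "BinGrid", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("effortTable", "HarmonizedEffort", function(x) x@effort)
#' @rdname accessors
#' @export
setMethod("abundanceComponents", "AbundanceField", function(x) x@components)
#' @rdname accessors
#' @export
setMethod("rateTable", "BycatchRates", function(x) x@rates)
#' @rdname accessors
#' @export
setMethod("excludedRecords", "BycatchRates", function(x) x@excluded)
#' @rdname accessors
#' @export
setMethod("summaryTable", "RateSummary", function(x) x@summary)
#' @rdname accessors
#' @export
setMethod("estimateTable", "BycatchEstimate", function(x) x@estimates)

setMethod("show", "BinGrid", function(object) {
  b <- object@bins
  cat("BinGrid:", nrow(b), "bins,", sum(b$coastal), "coastal;",
      "areas:", paste(sort(unique(stats::na.omit(b$area))), collapse = ", "), "\n")
})

setMethod("show", "VelocityField", function(object) {
  cat(sprintf("VelocityField: %d x %d grid, %d time steps [%s]\n",
              length(object@lon), length(object@lat), length(object@time),
              object@units))
})

setMethod("show", "Trajectories", function(object) {
  cat(sprintf("Trajectories: %d particles, %d stored steps (dt = %.4g d); status: %s\n",
              nrow(object@releases), length(object@time), object@step,
              paste(names(table(object@status)), table(object@status),
                    sep = "=", collapse = ", ")))
})

setMethod("show", "HarmonizedEffort", function(object) {
  e <- object@effort
  cat("HarmonizedEffort:", nrow(e), "rows;",
      "gears:", paste(unique(e$gear), collapse = ", "), ";",
      "years:", min(e$year), "-", max(e$year), "\n")
})

setMethod("show", "AbundanceField", function(object) {
  a <- object@components
  cat("AbundanceField:", nrow(a), "components;",
      "species:", paste(unique(a$species), collapse = ", "), ";",
      "annual survival:", object@survivalAnnual, "\n")
})

setMethod("show", "BycatchRates", function(object) {
  cat("BycatchRates:", nrow(object@rates), "rates (", object@by, "level ),",
      nrow(object@excluded), "excluded undefined-rate records\n")
})

setMethod("show", "RateSummary", function(object) {
  print(formatRateSummary(object))
})

setMethod("show", "BycatchEstimate", function(object) {
  e <- object@estimates
  cat("BycatchEstimate:", nrow(e), "species-gear-years\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf("SyntheticWorld: %d species, %d gears, years %d-%d, flow '%s', seed %d\n",
              nrow(object@species), length(unique(object@catchability$gear)),
              min(object@years), max(object@years), object@flow$name, object@seed))
})
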