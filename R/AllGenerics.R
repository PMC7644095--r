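#' @importFrom BiocGenerics start end width
#' @importFrom IRanges isDisjoint restrict coverage
NULL

#' @rdname ActivitySeries-class
#' @param object,x an object.
#' @export
setGeneric("flyId", function(x) standardGeneric("flyId"))
#' @rdname ActivitySeries-class
#' @export
setGeneric("activityCounts", function(x) standardGeneric("activityCounts"))
#' @rdname SleepBouts-class
#' @export
setGeneric("bouts", function(x) standardGeneric("bouts"))
#' @rdname MonitorTable-class
#' @export
setGeneric("monitorId", function(x) standardGeneric("monitorId"))
#' @rdname MonitorTable-class
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname MonitorTable-class
#' @export
setGeneric("flagged", function(x) standardGeneric("flagged"))

setMethod("flyId", "ActivitySeries", function(x) x@flyId)
setMethod("activityCounts", "ActivitySeries", function(x) x@counts)
setMethod("flagged", "ActivitySeries", function(x) x@flagged)
setMethod("bouts", "SleepBouts", function(x) x@bouts)
setMethod("monitorId", "MonitorTable", function(x) x@monitorId)
setMethod("timestamps", "MonitorTable", function(x) x@timestamps)
setMethod("flagged", "MonitorTable", function(x) x@flagged)
setMethod("activityCounts", "MonitorTable", function(x) x@counts)

#' @rdname MonitorTable-class
#' @export
setMethod("length", "MonitorTable", function(x) length(x@timestamps))
#' @rdname ActivitySeries-class
#' @export
setMethod("length", "ActivitySeries", function(x) length(x@counts))
#' @rdname SleepBouts-class
#' @export
setMethod("length", "SleepBouts", function(x) length(x@bouts))

setMethod("show", "MonitorTable", function(object) {
  cat("MonitorTable", object@monitorId, "\n",
      " rows:", length(object@timestamps),
      " span:", format(object@timestamps[1], "%Y-%m-%d %H:%M"), "..",
      format(object@timestamps[length(object@timestamps)], "%Y-%m-%d %H:%M"),
      "\n  flagged rows:", sum(object@flagged), "\n")
})

setMethod("show", "ActivitySeries", function(object) {
  cat("ActivitySeries", object@flyId,
      sprintf("(monitor %s, channel %d)\n", object@monitorId,
              object@channel),
      " ", length(object@counts), "min from",
      format(object@startTime, "%Y-%m-%d %H:%M"), "\n",
      " total counts:", sum(object@counts),
      " zero minutes:", sum(object@counts == 0L), "\n")
})

setMethod("show", "SleepBouts", function(object) {
  cat("SleepBouts:", length(object@bouts), "bouts over",
      object@sourceLen, "min",
      sprintf("(threshold %d min)\n", object@thresholdMin),
      " total sleep:", sum(width(object@bouts)), "min\n")
})

setMethod("show", "ExperimentDesign", function(object) {
  cat("ExperimentDesign: lights on", object@lightsOnClock,
      sprintf("(LD %g:%g), %d day(s)\n", object@lightHours,
              object@darkHours, object@nDays))
  if (!is.na(object@starvationStartZt))
    cat("  starvation from ZT", object@starvationStartZt, "on day",
        object@starvationDay, "\n")
})

setMethod("show", "Skeleton", function(object) {
  cat("Skeleton:", length(object@branches), "branch(es), root at (",
      object@root[1], ",", object@root[2], ") um\n")
})

setMethod("show", "DIResult", function(object) {
  cat(sprintf(
    "DIResult: DI = %.4f (%d of %d crossings outside a cone centred at %.2f deg)\n",
    object@di, object@total - object@inCone, object@total,
    object@coneCenterDeg))
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary:", object@genotype, "/", object@arm, "- n =",
      nrow(object@metrics), "flies, window [", object@window[1], ",",
      object@window[2], ") min\n")
})

#' @describeIn DIResult-class Defasciculation index value.
#' @param x a `DIResult`.
#' @export
di <- function(x) x@di
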