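#' @import methods
#' @importFrom IRanges IRanges
NULL

setOldClass("POSIXct")

#' Experiment design: photoperiod geometry and starvation anchor
#'
#' Describes the light-dark (LD) entrainment an activity recording was made
#' under and, optionally, when food deprivation began. Zeitgeber time (ZT) is
#' hours since lights-on: ZT0 = lights on, ZT `lightHours` = lights off.
#' Starvation time (ST) is hours since food deprivation began.
#'
#' @slot lightsOnClock local clock time mapped to ZT0, "HH:MM".
#' @slot lightHours,darkHours hours of light and dark per cycle; must sum
#'   to 24.
#' @slot starvationStartZt ZT in `[0, 24)` at which starvation starts, or
#'   `NA` for fed-only designs.
#' @slot starvationDay 1-based recording day on which starvation starts.
#' @slot nDays recording span in LD cycles.
#' @export
setClass("ExperimentDesign",
  representation(
    lightsOnClock = "character",
    lightHours = "numeric",
    darkHours = "numeric",
    starvationStartZt = "numeric",
    starvationDay = "integer",
    nDays = "integer"
  ),
  prototype(
    lightsOnClock = "06:30", lightHours = 12, darkHours = 12,
    starvationStartZt = NA_real_, starvationDay = 2L, nDays = 3L
  )
)

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (!grepl("^[0-2]?[0-9]:[0-5][0-9]$", object@lightsOnClock))
    msg <- c(msg, "lightsOnClock must be 'HH:MM'")
  if (!isTRUE(all.equal(object@lightHours + object@darkHours, 24)))
    msg <- c(msg, "lightHours + darkHours must equal 24")
  s <- object@starvationStartZt
  if (!is.na(s) && (s < 0 || s >= 24))
    msg <- c(msg, "starvationStartZt must lie in [0, 24)")
  if (object@nDays < 1L) msg <- c(msg, "nDays must be >= 1")
  if (object@starvationDay < 1L || object@starvationDay > object@nDays)
    msg <- c(msg, "starvationDay must lie in 1..nDays")
  if (length(msg)) msg else TRUE
})

#' @describeIn ExperimentDesign-class Constructor.
#' @param lightsOnClock,lightHours,darkHours,starvationStartZt,starvationDay,nDays
#'   see slots.
#' @export
experimentDesign <- function(lightsOnClock = "06:30", lightHours = 12,
                             darkHours = 24 - lightHours,
                             starvationStartZt = NA_real_,
                             starvationDay = 2L, nDays = 3L) {
  new("ExperimentDesign", lightsOnClock = lightsOnClock,
      lightHours = lightHours, darkHours = darkHours,
      starvationStartZt = as.numeric(starvationStartZt),
      starvationDay = as.integer(starvationDay), nDays = as.integer(nDays))
}

#' Validated DAM monitor table
#'
#' One Drosophila Activity Monitor (DAM) record: per-minute beam-break counts
#' for 32 channels, with minute-spaced timestamps. Rows whose status code is
#' not the valid-reading code are retained and flagged, never dropped.
#'
#' @slot monitorId opaque monitor label.
#' @slot timestamps `POSIXct` (naive local clock, stored as UTC), one per
#'   minute, strictly consecutive.
#' @slot status integer status codes; 1 is the valid-reading code.
#' @slot counts integer matrix, rows x 32 channels.
#' @slot flagged logical; `TRUE` where status != 1 or the row was inserted
#'   by gap repair.
#' @export
setClass("MonitorTable",
  representation(
    monitorId = "character",
    timestamps = "POSIXct",
    status = "integer",
    counts = "matrix",
    flagged = "logical"
  )
)

setValidity("MonitorTable", function(object) {
  n <- length(object@timestamps)
  msg <- character()
  if (n < 1L) msg <- c(msg, "monitor table must have at least one row")
  if (ncol(object@counts) != 32L) msg <- c(msg, "counts must have 32 channels")
  if (nrow(object@counts) != n || length(object@status) != n ||
      length(object@flagged) != n)
    msg <- c(msg, "row counts of timestamps, status, counts, flagged differ")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (n > 1L) {
    d <- diff(as.numeric(object@timestamps))
    bad <- which(d != 60)
    if (length(bad))
      msg <- c(msg, sprintf(
        "timestamps must be minute-spaced; rows %d and %d differ by %g s",
        bad[1], bad[1] + 1L, d[bad[1]]))
  }
  if (length(msg)) msg else TRUE
})

#' Per-fly minute-resolution activity series
#'
#' Beam-break counts for one fly, anchored to clock time: minute `i`
#' (1-based) covers `startTime + (i-1)` minutes. No gaps; the reader
#' enforces minute spacing before a series can be sliced out.
#'
#' @slot flyId opaque fly label.
#' @slot startTime `POSIXct` of the first minute.
#' @slot counts non-negative integer counts, one per minute.
#' @slot channel monitor channel 1-32.
#' @slot monitorId monitor label.
#' @slot flagged logical per minute (invalid status or repaired gap).
#' @export
setClass("ActivitySeries",
  representation(
    flyId = "character",
    startTime = "POSIXct",
    counts = "integer",
    channel = "integer",
    monitorId = "character",
    flagged = "logical"
  )
)

setValidity("ActivitySeries", function(object) {
  msg <- character()
  if (length(object@counts) < 1L) msg <- c(msg, "counts must have length >= 1")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (length(object@flagged) != length(object@counts))
    msg <- c(msg, "flagged must match counts in length")
  if (!is.na(object@channel) &&
      (object@channel < 1L || object@channel > 32L))
    msg <- c(msg, "channel must lie in 1..32")
  if (length(msg)) msg else TRUE
})

#' Sleep bouts of one activity series
#'
#' Maximal runs of consecutive zero-count minutes of length at least the
#' scoring threshold, held as an `IRanges` over 1-based minute indices
#' (a bout covering series minutes `[s, e)` in 0-based half-open
#' coordinates is the range `[s+1, e]`).
#'
#' @slot bouts `IRanges` of bout minutes, disjoint and sorted.
#' @slot sourceLen total minutes in the source series.
#' @slot thresholdMin scoring threshold in minutes.
#' @export
setClass("SleepBouts",
  representation(bouts = "IRanges", sourceLen = "integer",
                 thresholdMin = "integer")
)

setValidity("SleepBouts", function(object) {
  b <- object@bouts
  msg <- character()
  if (length(b)) {
    if (is.unsorted(BiocGenerics::start(b)) ||
        !IRanges::isDisjoint(b))
      msg <- c(msg, "bouts must be sorted and disjoint")
    if (min(BiocGenerics::start(b)) < 1L ||
        max(BiocGenerics::end(b)) > object@sourceLen)
      msg <- c(msg, "bouts must lie within 1..sourceLen")
    if (any(BiocGenerics::width(b) < object@thresholdMin))
      msg <- c(msg, "every bout must be at least thresholdMin long")
  }
  if (length(msg)) msg else TRUE
})

#' Rooted 2-D neurite skeleton
#'
#' A traced arbor in micrometers: the root is the point where the dorsal
#' ramification opens (the Sholl center), branches are polylines.
#'
#' @slot root numeric length-2, micrometers.
#' @slot branches list of n x 2 numeric matrices, each with >= 2 rows and
#'   no repeated consecutive points.
#' @export
setClass("Skeleton",
  representation(root = "numeric", branches = "list")
)

setValidity("Skeleton", function(object) {
  msg <- character()
  if (length(object@root) != 2L || !all(is.finite(object@root)))
    msg <- c(msg, "root must be a finite 2-D point")
  for (i in seq_along(object@branches)) {
    b <- object@branches[[i]]
    if (!is.matrix(b) || ncol(b) != 2L || nrow(b) < 2L) {
      msg <- c(msg, sprintf("branch %d must be an n>=2 x 2 matrix", i))
      next
    }
    if (!all(is.finite(b)))
      msg <- c(msg, sprintf("branch %d has non-finite coordinates", i))
    if (any(rowSums(abs(diff(b))) == 0))
      msg <- c(msg, sprintf("branch %d repeats consecutive points", i))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Skeleton-class Constructor.
#' @param root,branches see slots.
#' @export
skeleton <- function(root, branches) {
  branches <- lapply(branches, function(b) {
    b <- as.matrix(b)
    dimnames(b) <- NULL
    storage.mode(b) <- "double"
    b
  })
  new("Skeleton", root = as.numeric(root), branches = branches)
}

#' Cone-restricted Sholl configuration
#'
#' @slot nRings number of concentric circles (default 15).
#' @slot ringSpacingUm spacing between circles in micrometers (default 10).
#' @slot coneFullAngleDeg full apex angle of the cone in degrees (default
#'   15, i.e. +/- 7.5 degrees about the center line).
#' @slot orientationStepDeg grid resolution used only by the optional dense
#'   orientation scan; the default search is exact.
#' @slot tolUm geometric tolerance in micrometers.
#' @export
setClass("ShollConfig",
  representation(nRings = "integer", ringSpacingUm = "numeric",
                 coneFullAngleDeg = "numeric", orientationStepDeg = "numeric",
                 tolUm = "numeric"),
  prototype(nRings = 15L, ringSpacingUm = 10, coneFullAngleDeg = 15,
            orientationStepDeg = 0.1, tolUm = 1e-9)
)

setValidity("ShollConfig", function(object) {
  msg <- character()
  if (object@nRings < 1L) msg <- c(msg, "nRings must be >= 1")
  if (object@ringSpacingUm <= 0) msg <- c(msg, "ringSpacingUm must be > 0")
  if (object@coneFullAngleDeg <= 0 || object@coneFullAngleDeg >= 360)
    msg <- c(msg, "coneFullAngleDeg must lie in (0, 360)")
  if (length(msg)) msg else TRUE
})

#' @describeIn ShollConfig-class Constructor.
#' @param nRings,ringSpacingUm,coneFullAngleDeg,orientationStepDeg,tolUm
#'   see slots.
#' @export
shollConfig <- function(nRings = 15L, ringSpacingUm = 10,
                        coneFullAngleDeg = 15, orientationStepDeg = 0.1,
                        tolUm = 1e-9) {
  new("ShollConfig", nRings = as.integer(nRings),
      ringSpacingUm = ringSpacingUm, coneFullAngleDeg = coneFullAngleDeg,
      orientationStepDeg = orientationStepDeg, tolUm = tolUm)
}

#' Defasciculation index of one arbor
#'
#' `di = (total - inCone) / total`: the fraction of ring crossings that an
#' optimally oriented cone of the configured width cannot capture. 0 means
#' perfectly fasciculated (every crossing inside the best cone), values
#' toward 1 mean spread-out projections.
#'
#' @slot total total ring-crossing count.
#' @slot inCone crossings inside the best cone (the maximum over all cone
#'   orientations).
#' @slot di defasciculation index in `[0, 1]`.
#' @slot coneCenterDeg chosen cone center angle, degrees in `[0, 360)`.
#' @export
setClass("DIResult",
  representation(total = "integer", inCone = "integer", di = "numeric",
                 coneCenterDeg = "numeric")
)

setValidity("DIResult", function(object) {
  msg <- character()
  if (object@inCone > object@total) msg <- c(msg, "inCone cannot exceed total")
  if (object@total > 0L &&
      !isTRUE(all.equal(object@di,
                        (object@total - object@inCone) / object@total)))
    msg <- c(msg, "di must equal (total - inCone) / total")
  if (length(msg)) msg else TRUE
})

#' Per-fly sleep metrics for one cohort arm
#'
#' @slot genotype opaque genotype label.
#' @slot arm "fed" or "starved".
#' @slot metrics per-fly data.frame with columns `fly_id`,
#'   `total_sleep_min`, `bout_number`, `mean_bout_duration_min`.
#' @slot window the half-open minute window `[from, to)` the metrics
#'   summarize (0-based series minutes).
#' @export
setClass("CohortSummary",
  representation(genotype = "character", arm = "character",
                 metrics = "data.frame", window = "numeric")
)

setValidity("CohortSummary", function(object) {
  msg <- character()
  if (!object@arm %in% c("fed", "starved"))
    msg <- c(msg, "arm must be 'fed' or 'starved'")
  need <- c("fly_id", "total_sleep_min", "bout_number",
            "mean_bout_duration_min")
  if (!all(need %in% names(object@metrics)))
    msg <- c(msg, paste("metrics must have columns:",
                        paste(need, collapse = ", ")))
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be c(from, to) with from < to")
  if (length(msg)) msg else TRUE
})

#' Simulation parameters for the two-state sleep/wake chain
#'
#' A per-minute semi-Markov chain: an awake fly starts a sleep bout with
#' phase-dependent probability `pInitLight`/`pInitDark`; an asleep fly wakes
#' with probability `1/boutLenMean` of the phase (geometric bout lengths).
#' After the first LD shift following starvation start, the starved arm's
#' initiation probability is multiplied by `starvationInitMultiplier` —
#' starvation makes it harder to fall asleep without shortening bouts. An
#' optional `starvationDurMultiplier` scaling bout lengths exists but
#' defaults to 1 (off).
#'
#' @slot pInitLight,pInitDark per-minute bout-initiation probabilities.
#' @slot boutLenMeanLight,boutLenMeanDark mean bout lengths, minutes.
#' @slot starvationInitMultiplier factor in (0, 1] on initiation after the
#'   first post-starvation LD shift.
#' @slot starvationDurMultiplier factor on bout-length means (default 1).
#' @slot activeCountRate mean beam counts per awake minute (Poisson,
#'   truncated to >= 1 so awake minutes never read as sleep).
#' @export
setClass("SleepSimParams",
  representation(pInitLight = "numeric", pInitDark = "numeric",
                 boutLenMeanLight = "numeric", boutLenMeanDark = "numeric",
                 starvationInitMultiplier = "numeric",
                 starvationDurMultiplier = "numeric",
                 activeCountRate = "numeric"),
  prototype(pInitLight = 0.04, pInitDark = 0.10,
            boutLenMeanLight = 25, boutLenMeanDark = 40,
            starvationInitMultiplier = 0.5, starvationDurMultiplier = 1,
            activeCountRate = 2)
)

setValidity("SleepSimParams", function(object) {
  msg <- character()
  p <- c(object@pInitLight, object@pInitDark)
  if (any(p <= 0 | p >= 1))
    msg <- c(msg, "initiation probabilities must lie in (0, 1)")
  if (object@boutLenMeanLight < 1 || object@boutLenMeanDark < 1)
    msg <- c(msg, "bout length means must be >= 1 minute")
  m <- object@starvationInitMultiplier
  if (m <= 0 || m > 1)
    msg <- c(msg, "starvationInitMultiplier must lie in (0, 1]")
  if (object@starvationDurMultiplier <= 0)
    msg <- c(msg, "starvationDurMultiplier must be > 0")
  if (object@activeCountRate <= 0)
    msg <- c(msg, "activeCountRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SleepSimParams-class Constructor.
#' @param pInitLight,pInitDark,boutLenMeanLight,boutLenMeanDark see slots.
#' @param starvationInitMultiplier,starvationDurMultiplier,activeCountRate
#'   see slots.
#' @export
sleepSimParams <- function(pInitLight = 0.04, pInitDark = 0.10,
                           boutLenMeanLight = 25, boutLenMeanDark = 40,
                           starvationInitMultiplier = 0.5,
                           starvationDurMultiplier = 1,
                           activeCountRate = 2) {
  new("SleepSimParams", pInitLight = pInitLight, pInitDark = pInitDark,
      boutLenMeanLight = boutLenMeanLight, boutLenMeanDark = boutLenMeanDark,
      starvationInitMultiplier = starvationInitMultiplier,
      starvationDurMultiplier = starvationDurMultiplier,
      activeCountRate = activeCountRate)
}

#' Simulation parameters for synthetic arbors
#'
#' Branches leave the root with initial polar angles drawn about a trunk
#' direction (`Normal(trunkDeg, spreadSigmaDeg)`); each subsequent step of
#' `stepUm` micrometers turns by `Normal(0, wiggleDeg)`. Branch length
#' exceeds the default Sholl field (15 rings x 10 um) so straight rays
#' cross every ring.
#'
#' @slot nBranches number of branches.
#' @slot spreadSigmaDeg angular spread (SD, degrees) of initial directions.
#' @slot branchLenUm branch length in micrometers.
#' @slot stepUm polyline step length.
#' @slot wiggleDeg per-step angular noise SD, degrees.
#' @slot trunkDeg trunk direction, degrees.
#' @export
setClass("ArborSimParams",
  representation(nBranches = "integer", spreadSigmaDeg = "numeric",
                 branchLenUm = "numeric", stepUm = "numeric",
                 wiggleDeg = "numeric", trunkDeg = "numeric"),
  prototype(nBranches = 8L, spreadSigmaDeg = 15, branchLenUm = 160,
            stepUm = 2, wiggleDeg = 3, trunkDeg = 90)
)

setValidity("ArborSimParams", function(object) {
  msg <- character()
  if (object@nBranches < 1L) msg <- c(msg, "nBranches must be >= 1")
  if (object@spreadSigmaDeg < 0) msg <- c(msg, "spreadSigmaDeg must be >= 0")
  if (object@branchLenUm <= 0 || object@stepUm <= 0)
    msg <- c(msg, "branchLenUm and stepUm must be > 0")
  if (object@wiggleDeg < 0) msg <- c(msg, "wiggleDeg must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ArborSimParams-class Constructor.
#' @param nBranches,spreadSigmaDeg,branchLenUm,stepUm,wiggleDeg,trunkDeg
#'   see slots.
#' @export
arborSimParams <- function(nBranches = 8L, spreadSigmaDeg = 15,
                           branchLenUm = 160, stepUm = 2, wiggleDeg = 3,
                           trunkDeg = 90) {
  new("ArborSimParams", nBranches = as.integer(nBranches),
      spreadSigmaDeg = spreadSigmaDeg, branchLenUm = branchLenUm,
      stepUm = stepUm, wiggleDeg = wiggleDeg, trunkDeg = trunkDeg)
}
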