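# Sleep scoring and windowing.
#
# Sleep is the field-standard rule: any maximal run of >= 5 consecutive
# minutes with zero beam-break counts is one sleep bout. All window
# arithmetic below is in 0-based half-open series minutes [from, to),
# with series minute 0 assumed to fall at ZT0 of recording day 1 (the
# convention the synthetic generator emits; real recordings are sliced to
# it with sliceChannel).

#' Score sleep bouts from an activity series
#'
#' Finds every maximal run of consecutive zero-count minutes of length at
#' least `thresholdMin`. Scoring depends only on the zero/nonzero pattern
#' of the counts. Runs at the series edges are truncated at the recording
#' limits and still count when long enough.
#'
#' @param series an [ActivitySeries-class], or a bare non-negative integer
#'   vector of per-minute counts.
#' @param thresholdMin minimum run length in minutes (default 5).
#' @param treatFlaggedAsActive if `TRUE`, minutes flagged by the reader
#'   (invalid status, repaired gaps) are treated as active, so they can
#'   never be scored as sleep.
#' @return A [SleepBouts-class].
#' @examples
#' scoreSleep(c(0, 0, 0, 0, 0, 0, 2, 1, 0, 0, 0, 0, 0, 3))
#' @export
scoreSleep <- function(series, thresholdMin = 5L,
                       treatFlaggedAsActive = FALSE) {
  thresholdMin <- as.integer(thresholdMin)
  if (is.na(thresholdMin) || thresholdMin < 1L)
    stop("thresholdMin must be >= 1")
  if (is(series, "ActivitySeries")) {
    counts <- series@counts
    flg <- series@flagged
  } else {
    counts <- as.integer(series)
    flg <- rep(FALSE, length(counts))
  }
  if (!length(counts)) stop("empty series")
  if (anyNA(counts) || any(counts < 0L))
    stop("counts must be non-negative integers")
  z <- counts == 0L
  if (treatFlaggedAsActive) z <- z & !flg
  # run boundaries from the difference of the padded indicator
  d <- diff(c(0L, as.integer(z), 0L))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  keep <- (ends - starts + 1L) >= thresholdMin
  new("SleepBouts", bouts = IRanges(starts[keep], ends[keep]),
      sourceLen = length(counts), thresholdMin = thresholdMin)
}

#' Summarize sleep bouts over a window
#'
#' Clips bouts to the window and reports total sleep, the number of bouts
#' with nonzero overlap, and the mean of the overlapped portions. A bout
#' straddling the window boundary is counted once per window it overlaps,
#' so totals are conserved across adjacent windows. With zero bouts the
#' mean duration is `NA`, never 0 ("no sleep" is not "brief sleep").
#'
#' @param x a [SleepBouts-class].
#' @param window half-open minute interval `c(from, to)`, 0-based.
#' @return One-row `data.frame`: `total_sleep_min`, `bout_number`,
#'   `mean_bout_duration_min`, `window_from_min`, `window_to_min`.
#' @export
boutMetrics <- function(x, window = c(0, x@sourceLen)) {
  stopifnot(is(x, "SleepBouts"))
  window <- as.numeric(window)
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(from, to) with from < to")
  if (window[1] < 0 || window[2] > x@sourceLen)
    stop("window must lie within [0, sourceLen)")
  clipped <- IRanges::restrict(x@bouts, start = as.integer(window[1]) + 1L,
                               end = as.integer(window[2]),
                               keep.all.ranges = FALSE)
  w <- width(clipped)
  w <- w[w > 0L]
  data.frame(
    total_sleep_min = sum(w),
    bout_number = length(w),
    mean_bout_duration_min = if (length(w)) mean(w) else NA_real_,
    window_from_min = window[1], window_to_min = window[2]
  )
}

#' Per-bin sleep profile
#'
#' Minutes asleep per consecutive bin over a window, the per-genotype trace
#' plotted in fly sleep studies (30-min bins by convention). Bin sums are
#' conserved: they add up to the window's total sleep.
#'
#' @param x a [SleepBouts-class].
#' @param design an [ExperimentDesign-class] (used to label bins with ZT).
#' @param binMin bin width in minutes; must divide the window length.
#' @param window half-open minute interval `c(from, to)`, 0-based; default
#'   the full series.
#' @return `data.frame` with `bin_start_min`, `zt`, `minutes_asleep`
#'   (each in `[0, binMin]`).
#' @export
sleepProfile <- function(x, design, binMin = 30L,
                         window = c(0, x@sourceLen)) {
  stopifnot(is(x, "SleepBouts"), is(design, "ExperimentDesign"))
  binMin <- as.integer(binMin)
  window <- as.numeric(window)
  len <- window[2] - window[1]
  if (binMin < 1L || len %% binMin != 0)
    stop("binMin must be a positive divisor of the window length")
  if (window[1] < 0 || window[2] > x@sourceLen)
    stop("window must lie within [0, sourceLen)")
  nb <- len %/% binMin
  # per-minute sleep indicator over the window, then bin sums
  cov <- IRanges::coverage(x@bouts, width = x@sourceLen)
  asleep <- as.integer(as.vector(cov) > 0L)
  asleep <- asleep[(window[1] + 1L):window[2]]
  sums <- as.vector(rowsum(asleep, rep(seq_len(nb), each = binMin)))
  binStart <- window[1] + (seq_len(nb) - 1L) * binMin
  data.frame(bin_start_min = binStart,
             zt = (binStart / 60) %% 24,
             minutes_asleep = sums)
}

#' First light-dark transition after starvation start
#'
#' LD transitions occur at ZT0 (lights on) and ZT `lightHours` (lights
#' off). The first LD shift is the earliest transition strictly after
#' `starvationStartZt`; a starvation start exactly at a transition resolves
#' to the next one. For a ZT12 start in 12:12 LD this is lights-on at
#' ZT24/ZT0, so the post-shift 12 h are ZT0-ZT12 (the ST12-ST24 window).
#'
#' @param design an [ExperimentDesign-class] with `starvationStartZt` set.
#' @return list with `shiftZt` (ZT of the shift, in `[0, 24)`) and
#'   `stHours` (hours from starvation start to the shift).
#' @examples
#' firstLdShift(experimentDesign(starvationStartZt = 12))
#' @export
firstLdShift <- function(design) {
  stopifnot(is(design, "ExperimentDesign"))
  s <- design@starvationStartZt
  if (is.na(s)) stop("design has no starvation start")
  L <- design@lightHours
  shiftAbs <- if (s < L) L else 24
  list(shiftZt = shiftAbs %% 24, stHours = shiftAbs - s)
}

#' Map a starvation-time window to series minutes
#'
#' Converts an ST interval `[stFrom, stTo)` (hours since starvation onset)
#' to the half-open 0-based minute interval of a series whose minute 0 is
#' ZT0 of recording day 1.
#'
#' @param design an [ExperimentDesign-class] with `starvationStartZt` set.
#' @param stFrom,stTo starvation-time bounds in hours, `0 <= stFrom < stTo`.
#' @return numeric `c(from, to)` minutes.
#' @examples
#' d <- experimentDesign(starvationStartZt = 12)
#' stWindow(d, 12, 24)  # the ZT0-ZT12 light phase of the next cycle
#' @export
stWindow <- function(design, stFrom, stTo) {
  stopifnot(is(design, "ExperimentDesign"))
  s <- design@starvationStartZt
  if (is.na(s)) stop("design has no starvation start")
  if (stFrom < 0 || stFrom >= stTo)
    stop("need 0 <= stFrom < stTo")
  startMin <- (design@starvationDay - 1L) * 1440 + s * 60
  win <- startMin + c(stFrom, stTo) * 60
  if (win[2] > design@nDays * 1440)
    stop(sprintf("ST window [%g, %g) ends at minute %g, beyond the %d-day recording",
                 stFrom, stTo, win[2], design@nDays))
  win
}

#' Minute offset of starvation onset within an aligned series
#'
#' @param design an [ExperimentDesign-class] with `starvationStartZt` set.
#' @return series minute (0-based) at which starvation begins.
#' @export
starvationStartMin <- function(design) {
  s <- design@starvationStartZt
  if (is.na(s)) stop("design has no starvation start")
  (design@starvationDay - 1L) * 1440 + s * 60
}

#' Flag dead flies
#'
#' A configurable exclusion rule: a fly is called dead when its counts are
#' all zero over the final `finalHours` of the recording. Intended for fed
#' arms, where terminal all-zero activity is implausible sleep.
#'
#' @param seriesList list of [ActivitySeries-class].
#' @param finalHours span checked at the recording end (default 12).
#' @return logical vector, `TRUE` for flies to exclude.
#' @export
flagDeadFlies <- function(seriesList, finalHours = 12) {
  vapply(seriesList, function(s) {
    n <- length(s@counts)
    k <- min(n, round(finalHours * 60))
    all(s@counts[(n - k + 1L):n] == 0L)
  }, logical(1))
}
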