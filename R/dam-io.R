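# Reading, validating and slicing Drosophila Activity Monitor records.
#
# Two dialects are supported:
#   * "dam": the tab-delimited Trikinetics monitor layout — reading index,
#     date ("d b y"), time ("H:M:S"), status code, six device fields, then
#     32 per-channel beam-break counts (>= 42 columns).
#   * "csv": header "timestamp,ch1,...,ch32" with ISO-8601 minute
#     timestamps.
# Timestamps are naive local clock time; they are parsed in a fixed "UTC"
# zone so arithmetic is pure minute arithmetic, and the experiment design
# (not the file) defines lights-on.

.DAM_VALID_STATUS <- 1L

# month abbreviations are fixed, not locale-dependent
.parseDamDate <- function(date, time, line) {
  parts <- strsplit(trimws(date), "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("line %d: malformed DAM date '%s'", line[bad[1]],
                 date[bad[1]]))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  mon <- match(m[, 2], month.abb)
  if (anyNA(mon))
    stop(sprintf("line %d: unknown month abbreviation '%s'",
                 line[which(is.na(mon))[1]], m[which(is.na(mon))[1], 2]))
  yr <- as.integer(m[, 3])
  yr <- ifelse(yr < 100L, yr + 2000L, yr)
  ts <- as.POSIXct(sprintf("%04d-%02d-%02d %s", yr, mon,
                           as.integer(m[, 1]), time),
                   tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(ts))
    stop(sprintf("line %d: unparseable DAM timestamp '%s %s'",
                 line[which(is.na(ts))[1]], date[which(is.na(ts))[1]],
                 time[which(is.na(ts))[1]]))
  ts
}

.formatDamDate <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  sprintf("%d %s %02d", lt$mday, month.abb[lt$mon + 1L], lt$year %% 100L)
}

.validateMinuteSpacing <- function(ts, repair, status, counts, flagged) {
  d <- diff(as.numeric(ts))
  if (any(d <= 0)) {
    i <- which(d <= 0)[1]
    stop(sprintf(
      "non-monotone timestamps: row %d (%s) is not after row %d (%s)",
      i + 1L, format(ts[i + 1L], "%Y-%m-%d %H:%M"), i,
      format(ts[i], "%Y-%m-%d %H:%M")))
  }
  if (any(d != 60)) {
    i <- which(d != 60)[1]
    if (!repair)
      stop(sprintf(
        "gapped timestamps: rows %d and %d are %g min apart (%s .. %s); use repair = TRUE to insert flagged zero-count minutes",
        i, i + 1L, d[i] / 60, format(ts[i], "%Y-%m-%d %H:%M"),
        format(ts[i + 1L], "%Y-%m-%d %H:%M")))
    full <- seq(ts[1], ts[length(ts)], by = 60)
    idx <- match(as.numeric(full), as.numeric(ts))
    miss <- is.na(idx)
    outCounts <- matrix(0L, nrow = length(full), ncol = 32L)
    outCounts[!miss, ] <- counts
    outStatus <- rep(0L, length(full))
    outStatus[!miss] <- status
    outFlag <- rep(TRUE, length(full))
    outFlag[!miss] <- flagged
    return(list(timestamps = full, status = outStatus, counts = outCounts,
                flagged = outFlag))
  }
  list(timestamps = ts, status = status, counts = counts, flagged = flagged)
}

#' Read a DAM monitor file
#'
#' Parses a Trikinetics-style DAM monitor file or the equivalent CSV
#' dialect into a validated [MonitorTable-class]. Rows whose status code is
#' not the valid-reading code (1) are retained but flagged. Timestamps must
#' be strictly minute-spaced: a gap is an error unless `repair = TRUE`, in
#' which case missing minutes are inserted as flagged zero-count rows.
#'
#' @param path file to read.
#' @param dialect `"dam"` (tab-delimited Trikinetics layout, >= 42 columns)
#'   or `"csv"` (`timestamp,ch1,...,ch32` with ISO-8601 timestamps).
#' @param repair insert flagged zero-count rows at gaps instead of failing.
#' @param monitorId label for the monitor; defaults to the file name
#'   without extension.
#' @return A [MonitorTable-class].
#' @examples
#' d <- experimentDesign(starvationStartZt = 12)
#' flies <- simulateCohort(sleepSimParams(), d, nPerArm = 2, seed = 1)
#' tab <- monitorTableFromSeries(flies$fed, monitorId = "M1")
#' f <- tempfile(fileext = ".txt")
#' writeMonitorFile(tab, f, dialect = "dam")
#' readMonitorFile(f, dialect = "dam")
#' @export
readMonitorFile <- function(path, dialect = c("dam", "csv"), repair = FALSE,
                            monitorId = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(monitorId))
    monitorId <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no rows in ", path)

  if (dialect == "dam") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 42L)
    if (length(bad))
      stop(sprintf("line %d: expected >= 42 tab-separated columns, got %d",
                   bad[1], lengths(fields)[bad[1]]))
    m <- t(vapply(fields, function(f) f[1:42], character(42L)))
    ts <- .parseDamDate(m[, 2], m[, 3], seq_len(nrow(m)))
    status <- suppressWarnings(as.integer(m[, 4]))
    counts <- suppressWarnings(
      matrix(as.integer(m[, 11:42]), ncol = 32L))
    if (anyNA(status) || anyNA(counts)) {
      bad <- which(is.na(status) | rowSums(is.na(counts)) > 0)[1]
      stop(sprintf("line %d: non-integer status or count field", bad))
    }
  } else {
    header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    expect <- c("timestamp", paste0("ch", 1:32))
    if (length(header) != 33L || !all(trimws(header) == expect))
      stop("csv dialect requires header 'timestamp,ch1,...,ch32'")
    if (length(lines) < 2L) stop("no data rows in ", path)
    fields <- strsplit(lines[-1], ",", fixed = TRUE)
    bad <- which(lengths(fields) != 33L)
    if (length(bad))
      stop(sprintf("line %d: expected 33 comma-separated columns", bad[1] + 1L))
    m <- t(vapply(fields, identity, character(33L)))
    raw <- sub("T", " ", m[, 1], fixed = TRUE)
    ts <- as.POSIXct(raw, tz = "UTC",
                     tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
    if (anyNA(ts))
      stop(sprintf("line %d: unparseable timestamp '%s'",
                   which(is.na(ts))[1] + 1L, m[which(is.na(ts))[1], 1]))
    counts <- suppressWarnings(matrix(as.integer(m[, -1]), ncol = 32L))
    if (anyNA(counts)) {
      bad <- which(rowSums(is.na(counts)) > 0)[1]
      stop(sprintf("line %d: non-integer count field", bad + 1L))
    }
    status <- rep(.DAM_VALID_STATUS, nrow(counts))
  }
  if (any(counts < 0L)) {
    bad <- which(rowSums(counts < 0L) > 0)[1]
    stop(sprintf("row %d: negative count", bad))
  }
  flaggedRows <- status != .DAM_VALID_STATUS
  fixed <- .validateMinuteSpacing(ts, repair, status, counts, flaggedRows)
  new("MonitorTable", monitorId = monitorId,
      timestamps = fixed$timestamps, status = fixed$status,
      counts = fixed$counts, flagged = fixed$flagged)
}

#' Write a DAM monitor file
#'
#' Inverse of [readMonitorFile()]: `readMonitorFile(writeMonitorFile(t))`
#' reproduces counts and timestamps exactly.
#'
#' @param table a [MonitorTable-class].
#' @param path output file.
#' @param dialect `"dam"` or `"csv"`.
#' @export
writeMonitorFile <- function(table, path, dialect = c("dam", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(is(table, "MonitorTable"))
  validObject(table)
  n <- length(table@timestamps)
  if (n == 0L) stop("no rows")
  cnt <- apply(table@counts, 1L, paste, collapse = "\t")
  if (dialect == "dam") {
    lines <- paste(seq_len(n), .formatDamDate(table@timestamps),
                   format(table@timestamps, "%H:%M:%S", tz = "UTC"),
                   table@status,
                   "1\t0\t0\t0\t0\t0", cnt, sep = "\t")
  } else {
    cnt <- apply(table@counts, 1L, paste, collapse = ",")
    lines <- c(paste(c("timestamp", paste0("ch", 1:32)), collapse = ","),
               paste(format(table@timestamps, "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC"), cnt, sep = ","))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}

#' Extract one channel of a monitor table as an activity series
#'
#' @param table a [MonitorTable-class].
#' @param channel channel number, 1-32.
#' @param window closed timestamp interval `c(from, to)` (`POSIXct`), both
#'   endpoints inclusive at minute resolution, so a 60-minute slice is
#'   `c(t, t + 59 * 60)`. `NULL` (default) takes the full span.
#' @param flyId label for the resulting series.
#' @return An [ActivitySeries-class] of length equal to the window length
#'   in minutes.
#' @export
sliceChannel <- function(table, channel, window = NULL, flyId = NULL) {
  stopifnot(is(table, "MonitorTable"))
  channel <- as.integer(channel)
  if (is.na(channel) || channel < 1L || channel > 32L)
    stop("channel must lie in 1..32")
  ts <- table@timestamps
  if (is.null(window)) window <- c(ts[1], ts[length(ts)])
  if (length(window) != 2L)
    stop("window must be c(from, to)")
  window <- as.POSIXct(window, tz = "UTC")
  if (window[1] > window[2]) stop("window start must not be after its end")
  if (window[1] < ts[1] || window[2] > ts[length(ts)])
    stop(sprintf("window [%s, %s] extends outside the table span [%s, %s]",
                 format(window[1], "%Y-%m-%d %H:%M"),
                 format(window[2], "%Y-%m-%d %H:%M"),
                 format(ts[1], "%Y-%m-%d %H:%M"),
                 format(ts[length(ts)], "%Y-%m-%d %H:%M")))
  keep <- as.numeric(ts) >= as.numeric(window[1]) &
    as.numeric(ts) <= as.numeric(window[2])
  if (is.null(flyId))
    flyId <- sprintf("%s_ch%02d", table@monitorId, channel)
  new("ActivitySeries", flyId = flyId, startTime = window[1],
      counts = table@counts[keep, channel], channel = channel,
      monitorId = table@monitorId, flagged = table@flagged[keep])
}

#' Assemble a monitor table from activity series
#'
#' Packs up to 32 equal-length, equally anchored series into one
#' [MonitorTable-class] (unused channels are zero-filled), so synthetic
#' cohorts can exercise the real file writer and reader.
#'
#' @param seriesList list of [ActivitySeries-class], all sharing
#'   `startTime` and length; at most 32.
#' @param monitorId monitor label.
#' @param startChannel channel for the first series.
#' @export
monitorTableFromSeries <- function(seriesList, monitorId = "Monitor1",
                                   startChannel = 1L) {
  if (!length(seriesList)) stop("no series")
  n <- length(seriesList[[1]]@counts)
  t0 <- seriesList[[1]]@startTime
  if (startChannel + length(seriesList) - 1L > 32L)
    stop("more series than channels")
  counts <- matrix(0L, nrow = n, ncol = 32L)
  for (i in seq_along(seriesList)) {
    s <- seriesList[[i]]
    if (length(s@counts) != n || s@startTime != t0)
      stop("all series must share start time and length")
    counts[, startChannel + i - 1L] <- s@counts
  }
  new("MonitorTable", monitorId = monitorId,
      timestamps = seq(t0, by = 60, length.out = n),
      status = rep(.DAM_VALID_STATUS, n), counts = counts,
      flagged = rep(FALSE, n))
}
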