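# Independent oracles and fixture builders. Every oracle here is coded
# against the definition, not against the package's implementation path.

# Run-length-encoding sleep oracle: bouts as maximal zero runs >= threshold,
# returned as a data.frame of 1-based inclusive minute indices.
rleBouts <- function(counts, threshold = 5L) {
  r <- rle(counts == 0L)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values & r$lengths >= threshold
  data.frame(start = start[keep], end = end[keep])
}

# Per-minute membership oracle for window totals: counts minutes of
# [winFrom, winTo) (0-based) covered by any bout.
minuteOverlapTotal <- function(boutDf, winFrom, winTo, sourceLen) {
  asleep <- rep(FALSE, sourceLen)
  for (i in seq_len(nrow(boutDf)))
    asleep[boutDf$start[i]:boutDf$end[i]] <- TRUE
  sum(asleep[(winFrom + 1L):winTo])
}

# Dense-resampling crossing oracle: resample every branch at `step`
# micrometers of arc length and count sign changes of (distance - r).
denseCrossings <- function(skel, config, step = 0.01) {
  radii <- seq_len(config@nRings) * config@ringSpacingUm
  total <- 0L
  for (b in skel@branches) {
    seg <- sqrt(rowSums(diff(b)^2))
    s <- c(0, cumsum(seg))
    grid <- seq(0, s[length(s)], by = step)
    x <- approx(s, b[, 1], xout = grid)$y
    y <- approx(s, b[, 2], xout = grid)$y
    d <- sqrt((x - skel@root[1])^2 + (y - skel@root[2])^2)
    for (r in radii) {
      f <- d - r
      total <- total + sum(f[-1] * f[-length(f)] < 0)
    }
  }
  total
}

# Exhaustive left-edge cone oracle: a cone of width w anchored with its
# lower edge at each crossing angle; returns the maximal captured count.
leftEdgeConeMax <- function(angles, w) {
  best <- 0L
  for (a in angles) {
    rel <- (angles - a) %% 360
    best <- max(best, sum(rel <= w + 1e-9))
  }
  best
}

# Dense-grid orientation scan (a lower bound on the exact optimum).
gridConeMax <- function(angles, w, stepDeg = 0.05) {
  centers <- seq(0, 360 - stepDeg, by = stepDeg)
  max(vapply(centers, function(ctr)
    sum(abs((angles - ctr + 180) %% 360 - 180) <= w / 2 + 1e-9), 1L))
}

# Random, minute-spaced monitor table.
randomMonitorTable <- function(n = 1440L, seed = 1L, monitorId = "MonT") {
  set.seed(seed)
  counts <- matrix(rpois(n * 32L, 1.2), ncol = 32L)
  storage.mode(counts) <- "integer"
  status <- rep(1L, n)
  status[sample(n, max(1L, n %/% 100L))] <- 50L  # some flagged rows
  new("MonitorTable", monitorId = monitorId,
      timestamps = seq(as.POSIXct("2024-01-08 06:30:00", tz = "UTC"),
                       by = 60, length.out = n),
      status = status, counts = counts, flagged = status != 1L)
}

# Minimal well-formed DAM text lines.
damFixtureLines <- function(counts, status = rep(1L, nrow(counts)),
                            start = "2024-01-08 06:30:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  ts <- seq(t0, by = 60, length.out = nrow(counts))
  lt <- as.POSIXlt(ts, tz = "UTC")
  date <- sprintf("%d %s %02d", lt$mday, month.abb[lt$mon + 1L],
                  lt$year %% 100L)
  paste(seq_len(nrow(counts)), date, format(ts, "%H:%M:%S", tz = "UTC"),
        status, "1\t0\t0\t0\t0\t0",
        apply(counts, 1L, paste, collapse = "\t"), sep = "\t")
}

# Rotate a skeleton about its root by `deg` degrees.
rotateSkeleton <- function(skel, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  skeleton(skel@root, lapply(skel@branches, function(b)
    sweep(sweep(b, 2L, skel@root) %*% t(R), 2L, -skel@root)))
}

# Straight-ray skeleton through all rings at the given polar angles.
raySkeleton <- function(anglesDeg, len = 160) {
  skeleton(c(0, 0), lapply(anglesDeg * pi / 180, function(a)
    cbind(c(0, len * cos(a)), c(0, len * sin(a)))))
}
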