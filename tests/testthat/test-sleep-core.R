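test_that("scoreSleep finds maximal zero runs at or above the threshold", {
  b <- scoreSleep(rep(0L, 1440))
  expect_equal(length(b), 1L)
  expect_equal(BiocGenerics::start(bouts(b)), 1L)
  expect_equal(BiocGenerics::end(bouts(b)), 1440L)
  # zero runs of length 4 never score
  v <- rep(c(0L, 0L, 0L, 0L, 1L), 20)
  expect_equal(length(scoreSleep(v)), 0L)
  expect_equal(boutMetrics(scoreSleep(v))$total_sleep_min, 0)
  expect_error(scoreSleep(integer()), "empty")
  expect_error(scoreSleep(c(1L, -1L)), "non-negative")
})

test_that("scoreSleep agrees with an independent RLE oracle on random series", {
  set.seed(11)
  for (i in 1:200) {
    v <- rbinom(1440, 1, runif(1, 0.2, 0.8)) * rpois(1440, 2)
    b <- bouts(scoreSleep(v))
    o <- rleBouts(v)
    expect_identical(BiocGenerics::start(b), o$start)
    expect_identical(BiocGenerics::end(b), o$end)
  }
})

test_that("scoring depends only on the zero pattern and shifts with the series", {
  set.seed(5)
  for (i in 1:25) {
    v <- rbinom(500, 1, 0.5) * rpois(500, 3)
    expect_identical(bouts(scoreSleep(v)),
                     bouts(scoreSleep(v * 17L)))  # count rescaling
    k <- sample(1:50, 1)
    shifted <- c(rep(1L, k), v)
    bs <- bouts(scoreSleep(shifted))
    bo <- IRanges::shift(bouts(scoreSleep(v)), k)
    expect_identical(bs, bo)  # translation equivariance
  }
})

test_that("bouts are monotone in the threshold (as minute sets)", {
  set.seed(6)
  for (i in 1:25) {
    v <- rbinom(800, 1, 0.6) * rpois(800, 2)
    b1 <- bouts(scoreSleep(v, 3L))
    b2 <- bouts(scoreSleep(v, 8L))
    # every minute asleep at the stricter threshold is asleep at the laxer
    ov <- IRanges::findOverlaps(b2, b1, type = "within")
    expect_equal(length(S4Vectors::queryHits(ov)), length(b2))
  }
})

test_that("boutMetrics clips at window boundaries and conserves totals", {
  b <- new("SleepBouts", bouts = IRanges::IRanges(1L, 100L),
           sourceLen = 1440L, thresholdMin = 5L)
  m <- boutMetrics(b, c(0, 1440))
  expect_equal(m$total_sleep_min, 100)
  expect_equal(m$bout_number, 1L)
  expect_equal(m$mean_bout_duration_min, 100)
  # bout [700, 760) clipped by window [0, 720)
  b2 <- new("SleepBouts", bouts = IRanges::IRanges(701L, 760L),
            sourceLen = 1440L, thresholdMin = 5L)
  m2 <- boutMetrics(b2, c(0, 720))
  expect_equal(m2$total_sleep_min, 20)
  expect_equal(m2$bout_number, 1L)
  expect_equal(m2$mean_bout_duration_min, 20)
  # no overlapping bouts: mean duration is missing, not zero
  m3 <- boutMetrics(b2, c(0, 600))
  expect_equal(m3$bout_number, 0L)
  expect_true(is.na(m3$mean_bout_duration_min))
  expect_error(boutMetrics(b, c(100, 100)), "window")
})

test_that("window totals match a per-minute membership oracle", {
  set.seed(12)
  for (i in 1:30) {
    v <- rbinom(1440, 1, 0.6) * rpois(1440, 2)
    sb <- scoreSleep(v)
    o <- rleBouts(v)
    w <- sort(sample(0:1440, 2))
    if (w[1] == w[2]) next
    expect_equal(boutMetrics(sb, w)$total_sleep_min,
                 minuteOverlapTotal(o, w[1], w[2], 1440L))
    # adjacent windows conserve the total
    mid <- w[1] + (w[2] - w[1]) %/% 2
    if (mid > w[1] && mid < w[2])
      expect_equal(boutMetrics(sb, c(w[1], mid))$total_sleep_min +
                     boutMetrics(sb, c(mid, w[2]))$total_sleep_min,
                   boutMetrics(sb, w)$total_sleep_min)
  }
})

test_that("sleep profiles bin correctly and conserve bout totals", {
  d <- experimentDesign()
  allAsleep <- scoreSleep(rep(0L, 1440))
  pr <- sleepProfile(allAsleep, d, binMin = 30L, window = c(0, 1440))
  expect_equal(nrow(pr), 48L)
  expect_true(all(pr$minutes_asleep == 30))
  noSleep <- scoreSleep(rep(1L, 1440))
  expect_true(all(sleepProfile(noSleep, d)$minutes_asleep == 0))
  expect_error(sleepProfile(allAsleep, d, binMin = 7L), "divisor")
  set.seed(13)
  for (i in 1:20) {
    v <- rbinom(1440, 1, 0.5) * rpois(1440, 2)
    sb <- scoreSleep(v)
    pr <- sleepProfile(sb, d)
    expect_true(all(pr$minutes_asleep >= 0 & pr$minutes_asleep <= 30))
    expect_equal(sum(pr$minutes_asleep),
                 boutMetrics(sb, c(0, 1440))$total_sleep_min)
  }
})

test_that("the first LD shift is the earliest transition strictly after starvation", {
  cases <- list(c(0, 12, 12), c(6, 12, 6), c(12, 0, 12), c(18, 0, 6))
  for (cs in cases) {
    sh <- firstLdShift(experimentDesign(starvationStartZt = cs[1]))
    expect_equal(sh$shiftZt, cs[2])
    expect_equal(sh$stHours, cs[3])
  }
  expect_error(firstLdShift(experimentDesign()), "no starvation start")
})

test_that("ST windows map to series minutes per the ZT12-start convention", {
  d <- experimentDesign(starvationStartZt = 12)  # starvation day 2
  # ST12-ST24 is the ZT0-ZT12 light phase of the next cycle: day-3 minutes
  expect_equal(stWindow(d, 12, 24), c(2 * 1440, 2 * 1440 + 720))
  expect_equal(diff(stWindow(d, 0, 0.5)), 30)
  expect_equal(c(stWindow(d, 0, 12)[1], stWindow(d, 12, 24)[2]),
               stWindow(d, 0, 24))
  expect_error(stWindow(d, 24, 48), "beyond")
  expect_error(stWindow(d, 5, 3))
})

test_that("flagged minutes can be excluded from sleep and dead flies flagged", {
  s <- new("ActivitySeries", flyId = "f", channel = 1L, monitorId = "m",
           startTime = as.POSIXct("2024-01-01 06:30", tz = "UTC"),
           counts = rep(0L, 60), flagged = rep(c(FALSE, TRUE), each = 30))
  expect_equal(boutMetrics(scoreSleep(s))$total_sleep_min, 60)
  expect_equal(boutMetrics(scoreSleep(s, treatFlaggedAsActive = TRUE))$
                 total_sleep_min, 30)
  alive <- new("ActivitySeries", flyId = "a", channel = 1L, monitorId = "m",
               startTime = s@startTime,
               counts = rep(c(0L, 1L), 720), flagged = rep(FALSE, 1440))
  dead <- new("ActivitySeries", flyId = "d", channel = 1L, monitorId = "m",
              startTime = s@startTime,
              counts = c(rep(1L, 720), rep(0L, 720)),
              flagged = rep(FALSE, 1440))
  expect_equal(flagDeadFlies(list(alive, dead), finalHours = 12),
               c(FALSE, TRUE))
})
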