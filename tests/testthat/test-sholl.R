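test_that("SWC skeletons reconstruct polylines from parent links", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 1 0 0 0 1 -1",
               "2 0 0 10 0 1 1",
               "3 0 0 20 0 1 2"), f)
  sk <- readSkeleton(f, "swc")
  expect_length(sk@branches, 1L)
  expect_equal(nrow(sk@branches[[1]]), 3L)
  expect_equal(sk@root, c(0, 0))
  # a branch point splits into two polylines sharing that node
  writeLines(c("1 1 0 0 0 1 -1",
               "2 0 0 10 0 1 1",
               "3 0 -5 20 0 1 2",
               "4 0 5 20 0 1 2"), f)
  sk2 <- readSkeleton(f, "swc")
  expect_length(sk2@branches, 3L)  # root->2, 2->3, 2->4
  shared <- vapply(sk2@branches[2:3], function(b) all(b[1, ] == c(0, 10)),
                   TRUE)
  expect_true(all(shared))
  writeLines(c("1 1 0 0 0 1 -1", "2 0 0 10 0 1 9"), f)
  expect_error(readSkeleton(f, "swc"), "orphan")
})

test_that("skeleton writers and readers are mutually inverse", {
  set.seed(21)
  for (i in 1:10) {
    sk <- generateArbor(arborSimParams(nBranches = 4L, spreadSigmaDeg = 30),
                        seed = 100 + i)
    fc <- withr::local_tempfile(fileext = ".csv")
    writeSkeleton(sk, fc, "csv_polyline")
    back <- readSkeleton(fc, "csv_polyline")
    expect_identical(back@root, sk@root)
    expect_identical(back@branches, sk@branches)
    fs <- withr::local_tempfile(fileext = ".swc")
    writeSkeleton(sk, fs, "swc")
    back2 <- readSkeleton(fs, "swc")
    expect_equal(back2@root, sk@root)
    expect_equal(back2@branches, sk@branches)
  }
})

test_that("ring crossings follow the geometry of radial segments", {
  cfg <- shollConfig()
  # radial segment from 5 um to 25 um crosses rings 1 and 2 (radii 10, 20)
  sk <- skeleton(c(0, 0), list(cbind(c(5, 25), c(0, 0))))
  cr <- ringIntersections(sk, cfg)
  expect_equal(sort(cr$ring), c(1L, 2L))
  expect_equal(cr$angle_deg, c(0, 0))
  expect_equal(sort(cr$x), c(10, 20))
  # entirely inside ring 1: empty set is legal
  sk2 <- skeleton(c(0, 0), list(cbind(c(1, 5), c(2, 3))))
  expect_equal(nrow(ringIntersections(sk2, cfg)), 0L)
  # offset root: same geometry translated
  sk3 <- skeleton(c(100, -50), list(cbind(c(105, 125), c(-50, -50))))
  cr3 <- ringIntersections(sk3, cfg)
  expect_equal(sort(cr3$x), c(110, 120))
  # a vertex lying exactly on a ring is one crossing, not two
  sk4 <- skeleton(c(0, 0), list(cbind(c(5, 10, 15), c(0, 0, 0))))
  cr4 <- ringIntersections(sk4, cfg)
  expect_equal(nrow(cr4[cr4$ring == 1L, ]), 1L)
})

test_that("crossing counts match a dense-resampling oracle on random arbors", {
  cfg <- shollConfig()
  for (i in 1:20) {
    sk <- generateArbor(arborSimParams(nBranches = 5L,
                                       spreadSigmaDeg = 10 * (i %% 4 + 1)),
                        seed = 300 + i)
    expect_equal(nrow(ringIntersections(sk, cfg)),
                 denseCrossings(sk, cfg, step = 0.01))
  }
})

test_that("bestCone attains the exact optimum with documented tie handling", {
  cfg <- shollConfig()
  # all crossings at one angle: that angle is returned, count = total
  one <- data.frame(angle_deg = rep(40, 7))
  bc <- bestCone(one, cfg)
  expect_equal(bc$inCone, 7L)
  expect_equal(bc$coneCenterDeg, 40)
  # two crossings 180 degrees apart: a 15-degree cone captures one
  two <- data.frame(angle_deg = c(10, 190))
  bc2 <- bestCone(two, cfg)
  expect_equal(bc2$inCone, 1L)
  expect_equal(bc2$coneCenterDeg, 10)  # smallest-angle tie-break
  expect_error(bestCone(data.frame(angle_deg = numeric()), cfg),
               "DI undefined")
  # random angle sets: equal to the exhaustive left-edge anchor oracle and
  # never below the dense-grid lower bound
  set.seed(33)
  for (i in 1:50) {
    ang <- runif(sample(3:40, 1), 0, 360)
    got <- bestCone(data.frame(angle_deg = ang), cfg)$inCone
    expect_equal(got, leftEdgeConeMax(ang, cfg@coneFullAngleDeg))
    expect_gte(got, gridConeMax(ang, cfg@coneFullAngleDeg))
  }
})

test_that("analytic DI cases and the undefined-DI error", {
  # one straight ray through all 15 rings: everything in the cone
  r1 <- defasciculationIndex(raySkeleton(90))
  expect_equal(r1@total, 15L)
  expect_equal(r1@inCone, 15L)
  expect_equal(r1@di, 0)
  # two opposite full-length rays: half the crossings escape any 15-deg cone
  r2 <- defasciculationIndex(raySkeleton(c(90, 270)))
  expect_equal(r2@total, 30L)
  expect_equal(r2@inCone, 15L)
  expect_equal(r2@di, 0.5)
  # no crossings -> an error, never DI = 0
  tiny <- skeleton(c(0, 0), list(cbind(c(0, 1), c(0, 1))))
  expect_error(defasciculationIndex(tiny), "DI undefined")
})

test_that("DI is conserved, rotation-invariant and scale-covariant", {
  set.seed(44)
  for (i in 1:15) {
    sk <- generateArbor(arborSimParams(nBranches = 6L, spreadSigmaDeg = 25),
                        seed = 400 + i)
    r <- defasciculationIndex(sk)
    expect_identical(r@inCone + (r@total - r@inCone), r@total)
    rot <- runif(1, 0, 360)
    rr <- defasciculationIndex(rotateSkeleton(sk, rot))
    expect_equal(rr@di, r@di, tolerance = 1e-12)
    expect_identical(rr@total, r@total)
    delta <- (rr@coneCenterDeg - r@coneCenterDeg - rot) %% 360
    expect_lt(min(delta, 360 - delta), 1e-6)
    # scaling skeleton and ring spacing together changes nothing
    k <- runif(1, 0.5, 3)
    scaled <- skeleton(sk@root * k, lapply(sk@branches, function(b) b * k))
    rs <- defasciculationIndex(scaled,
                               shollConfig(ringSpacingUm = 10 * k))
    expect_identical(rs@total, r@total)
    expect_equal(rs@di, r@di, tolerance = 1e-12)
  }
})

test_that("DI is non-increasing in the cone width", {
  set.seed(55)
  for (i in 1:15) {
    sk <- generateArbor(arborSimParams(nBranches = 6L, spreadSigmaDeg = 30),
                        seed = 500 + i)
    dis <- vapply(c(5, 15, 45, 90, 180),
                  function(w) defasciculationIndex(
                    sk, shollConfig(coneFullAngleDeg = w))@di, 1)
    expect_true(all(diff(dis) <= 1e-12))
  }
})

test_that("diBatch flags failing skeletons and summarizes groups", {
  sk <- raySkeleton(c(80, 100))
  empty <- skeleton(c(0, 0), list(cbind(c(0, 1), c(0, 1))))
  out <- diBatch(list(a = sk, b = empty, c = raySkeleton(90)),
                 groups = c("g1", "g1", "g2"))
  expect_equal(nrow(out$rows), 3L)
  expect_true(nzchar(out$rows$flag[out$rows$label == "b"]))
  expect_true(is.na(out$rows$di[out$rows$label == "b"]))
  # group mean recomputes from the rows
  g1 <- out$rows$di[out$rows$group == "g1" & !is.na(out$rows$di)]
  expect_equal(out$summary$mean_di[out$summary$group == "g1"], mean(g1))
  one <- diBatch(list(only = sk))
  expect_equal(nrow(one$rows), 1L)
})
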