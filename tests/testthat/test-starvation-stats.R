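makeCohort <- function(totals, arm, genotype = "wt", window = c(0, 720)) {
  new("CohortSummary", genotype = genotype, arm = arm,
      metrics = data.frame(
        fly_id = sprintf("f%02d", seq_along(totals)),
        total_sleep_min = totals,
        bout_number = pmax(1L, round(totals / 25)),
        mean_bout_duration_min = 25),
      window = window)
}

test_that("sleep loss is the relative drop in group-mean sleep", {
  r <- sleepLossPct(makeCohort(c(590, 600, 610), "fed"),
                    makeCohort(c(260, 270, 280), "starved"))
  expect_equal(r$loss_pct, 55.0)
  expect_equal(r$fed_mean_min, 600)
  # negative loss is allowed (starved flies sleeping slightly more)
  r2 <- sleepLossPct(makeCohort(c(499, 500, 501), "fed"),
                     makeCohort(c(501, 502, 503), "starved"))
  expect_equal(r2$loss_pct, -0.4)
  # scale invariance: multiplying all minutes by k leaves loss unchanged
  r3 <- sleepLossPct(makeCohort(3 * c(590, 600, 610), "fed"),
                     makeCohort(3 * c(260, 270, 280), "starved"))
  expect_equal(r3$loss_pct, r$loss_pct)
  expect_error(sleepLossPct(makeCohort(c(0, 0), "fed"),
                            makeCohort(c(1, 2), "starved")), "undefined")
  expect_error(sleepLossPct(makeCohort(1:3, "fed"),
                            makeCohort(1:3, "starved", window = c(0, 100))),
               "window")
  expect_error(sleepLossPct(makeCohort(1:3, "fed", genotype = "a"),
                            makeCohort(1:3, "starved", genotype = "b")),
               "genotype")
})

test_that("two-sample t matches the textbook formula and its conventions", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- compareTwo(a, b, "student_t")
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  tManual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$statistic, tManual, tolerance = 1e-10)
  expect_equal(r$p_value, 2 * pt(-abs(tManual), 4), tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  r0 <- compareTwo(a, a)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # swapping negates the statistic, p unchanged
  rs <- compareTwo(b, a, "student_t")
  expect_equal(rs$statistic, -r$statistic)
  expect_equal(rs$p_value, r$p_value)
  # degenerate zero-variance samples with equal means
  rd <- compareTwo(c(2, 2, 2), c(2, 2, 2))
  expect_equal(rd$statistic, 0)
  expect_equal(rd$p_value, 1)
  expect_error(compareTwo(1, c(1, 2)), "n >= 2")
  # Welch's variant uses Welch degrees of freedom
  rw <- compareTwo(c(1, 2, 3, 9), b, "welch_t")
  expect_equal(rw$p_value,
               t.test(c(1, 2, 3, 9), b)$p.value, tolerance = 1e-12)
})

test_that("one-way ANOVA F matches hand-computed mean squares", {
  g <- list(a = c(1, 2, 3), b = c(2, 4, 6), c = c(5, 7, 9))
  y <- unlist(g); gm <- mean(y)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  fManual <- (ssb / 2) / (ssw / 6)
  for (m in c("anova_tukey", "anova_dunnett")) {
    r <- compareMany(g, control = "a", method = m)
    expect_equal(r$f_statistic, fManual, tolerance = 1e-10)
    expect_equal(r$df_between, 2)
    expect_equal(r$df_within, 6)
  }
})

test_that("post-hoc contrasts follow the Dunnett/Tukey contracts", {
  g <- list(ctrl = c(1, 2, 3), x = c(1, 2, 3), y = c(1, 2, 3))
  # identical groups: F = 0, all adjusted p = 1
  rt <- compareMany(g, method = "anova_tukey")
  expect_equal(rt$f_statistic, 0)
  expect_true(all(rt$contrasts$p_adj == 1))
  rd <- compareMany(g, control = "ctrl", method = "anova_dunnett")
  expect_equal(rd$f_statistic, 0)
  expect_true(all(rd$contrasts$p_adj > 0.9999))
  expect_equal(nrow(rd$contrasts), 2L)  # each group vs control
  expect_equal(nrow(rt$contrasts), 3L)  # all pairs
  # two groups: Tukey collapses to the two-sample result
  g2 <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  r2 <- compareMany(g2, method = "anova_tukey")
  expect_equal(r2$contrasts$p_adj, compareTwo(g2$a, g2$b)$p_value,
               tolerance = 1e-4)  # ptukey is itself numerically integrated
  expect_error(compareMany(g2, method = "anova_dunnett"), "control")
  # adjusted p >= unadjusted pairwise p for the same contrast
  set.seed(9)
  for (i in 1:10) {
    gg <- list(a = rnorm(6), b = rnorm(6, 0.5), c = rnorm(6, 1))
    rT <- compareMany(gg, method = "anova_tukey")
    rD <- compareMany(gg, control = "a", method = "anova_dunnett")
    pAB <- compareTwo(gg$a, gg$b)$p_value
    expect_gte(rT$contrasts$p_adj[rT$contrasts$contrast == "b-a"],
               pAB * (1 - 1e-6))
    expect_gte(rD$contrasts$p_adj[grepl("^b", rD$contrasts$contrast)],
               pAB * (1 - 0.02))  # Dunnett p is quasi-MC integrated
  }
})

test_that("Dunnett p-values are reproducible and leave the caller's RNG alone", {
  g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(4, 5, 6, 7))
  set.seed(123); before <- runif(1)
  set.seed(123)
  r1 <- compareMany(g, control = "a", method = "anova_dunnett")
  after <- runif(1)
  expect_equal(after, before)  # RNG state restored
  r2 <- compareMany(g, control = "a", method = "anova_dunnett")
  expect_identical(r1$contrasts$p_adj, r2$contrasts$p_adj)
})

test_that("a full experiment summary reproduces the programmed effect structure", {
  d <- experimentDesign(starvationStartZt = 12)
  p <- sleepSimParams()
  co <- simulateCohort(p, d, nPerArm = 32, seed = 2024)
  res <- summarizeExperiment(list(wt = co), d)
  expect_equal(nrow(res$loss), 1L)
  expect_equal(res$loss$genotype, "wt")
  expect_gt(res$loss$loss_pct, 0)
  bd <- res$bout_decomposition
  post <- bd[bd$phase == "post_shift", ]
  # fewer bouts after the shift in the starved arm...
  expect_lt(post$mean_bout_number[post$arm == "starved"],
            post$mean_bout_number[post$arm == "fed"])
  # ...with essentially unchanged bout duration
  win <- stWindow(d, 12, 24)
  fedDur <- vapply(co$fed, function(s)
    boutMetrics(scoreSleep(s), win)$mean_bout_duration_min, 1)
  stvDur <- vapply(co$starved, function(s)
    boutMetrics(scoreSleep(s), win)$mean_bout_duration_min, 1)
  expect_gt(compareTwo(fedDur, stvDur)$p_value, 0.01)
  fedN <- vapply(co$fed, function(s)
    boutMetrics(scoreSleep(s), win)$bout_number, 1L)
  stvN <- vapply(co$starved, function(s)
    boutMetrics(scoreSleep(s), win)$bout_number, 1L)
  expect_lt(compareTwo(as.numeric(fedN), as.numeric(stvN))$p_value, 0.05)
})

test_that("multi-genotype summaries emit Dunnett contrasts vs the control", {
  d <- experimentDesign(starvationStartZt = 12)
  co1 <- simulateCohort(sleepSimParams(), d, nPerArm = 6, seed = 31)
  co2 <- simulateCohort(sleepSimParams(starvationInitMultiplier = 0.9), d,
                        nPerArm = 6, seed = 32)
  res <- summarizeExperiment(list(wt = co1, mut = co2), d, control = "wt")
  expect_equal(sort(res$loss$genotype), c("mut", "wt"))
  expect_true(!is.null(res$posthoc))
  expect_equal(nrow(res$posthoc), 1L)  # one genotype vs control
  expect_error(summarizeExperiment(list(wt = list(fed = co1$fed)), d),
               "missing")
})
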