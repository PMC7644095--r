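# Starvation-induced sleep loss and the group comparisons used in fly
# sleep experiments: two-sample t tests per genotype, one-way ANOVA with
# Dunnett (each vs control) or Tukey (all pairs) post-hoc across groups.

#' Build a cohort summary from per-fly series
#'
#' Scores every series and summarizes the given window, producing the
#' per-arm container the loss and comparison functions consume.
#'
#' @param seriesList list of [ActivitySeries-class].
#' @param window half-open minute interval `c(from, to)`, 0-based.
#' @param arm `"fed"` or `"starved"`.
#' @param genotype genotype label.
#' @param thresholdMin sleep-scoring threshold, minutes.
#' @return A [CohortSummary-class].
#' @export
summarizeCohort <- function(seriesList, window, arm, genotype = "wt",
                            thresholdMin = 5L) {
  if (!length(seriesList)) stop("empty cohort")
  rows <- lapply(seriesList, function(s) {
    m <- boutMetrics(scoreSleep(s, thresholdMin = thresholdMin), window)
    cbind(fly_id = s@flyId, m[, c("total_sleep_min", "bout_number",
                                  "mean_bout_duration_min")])
  })
  new("CohortSummary", genotype = genotype, arm = arm,
      metrics = do.call(rbind, rows), window = as.numeric(window))
}

#' Starvation-induced sleep loss
#'
#' `loss_pct = 100 * (fed_mean - starved_mean) / fed_mean` on the group
#' means of total sleep over a shared window. Negative values are allowed
#' and meaningful (flies that sleep more when starved).
#'
#' @param fed,starved [CohortSummary-class] objects for the same genotype
#'   and window.
#' @return One-row `data.frame`: `genotype`, `n_fed`, `n_starved`,
#'   `fed_mean_min`, `starved_mean_min`, `loss_pct`, `window_from_min`,
#'   `window_to_min`.
#' @export
sleepLossPct <- function(fed, starved) {
  stopifnot(is(fed, "CohortSummary"), is(starved, "CohortSummary"))
  if (fed@arm != "fed" || starved@arm != "starved")
    stop("arguments must be the fed and starved arms, in that order")
  if (fed@genotype != starved@genotype)
    stop("cohorts are from different genotypes")
  if (!isTRUE(all.equal(fed@window, starved@window)))
    stop("cohorts summarize different windows")
  fm <- mean(fed@metrics$total_sleep_min)
  sm <- mean(starved@metrics$total_sleep_min)
  if (fm == 0) stop("fed mean sleep is 0; loss percentage is undefined")
  data.frame(genotype = fed@genotype,
             n_fed = nrow(fed@metrics), n_starved = nrow(starved@metrics),
             fed_mean_min = fm, starved_mean_min = sm,
             loss_pct = 100 * (fm - sm) / fm,
             window_from_min = fed@window[1],
             window_to_min = fed@window[2])
}

#' Two-sample comparison
#'
#' Student's (equal-variance) or Welch's two-sided t test. The statistic's
#' sign follows `mean(a) - mean(b)`. When both samples are constant with
#' equal means the test is degenerate and reported as `t = 0`, `p = 1`.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param method `"student_t"` or `"welch_t"`.
#' @return One-row `data.frame`: `statistic`, `df`, `p_value`, `method`,
#'   `contrast`.
#' @export
compareTwo <- function(a, b, method = c("student_t", "welch_t")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs n >= 2")
  if (anyNA(a) || anyNA(b)) stop("samples contain NA")
  out <- function(stat, df, p)
    data.frame(statistic = stat, df = df, p_value = p, method = method,
               contrast = "a-b")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      df <- if (method == "student_t") length(a) + length(b) - 2 else NA_real_
      return(out(0, df, 1))
    }
    return(out(sign(mean(a) - mean(b)) * Inf,
               length(a) + length(b) - 2, 0))
  }
  tt <- stats::t.test(a, b, var.equal = method == "student_t")
  out(unname(tt$statistic), unname(tt$parameter), tt$p.value)
}

#' One-way ANOVA with Dunnett or Tukey contrasts
#'
#' Omnibus one-way ANOVA plus multiplicity-adjusted post-hoc contrasts:
#' Dunnett compares every group against a named control, Tukey compares
#' all pairs. Tukey adjusted p-values come from the studentized range
#' distribution; Dunnett from the multivariate t (the quasi-random
#' integration is run under a fixed internal RNG state, so results are
#' reproducible and the caller's RNG is untouched).
#'
#' @param groups named list of numeric samples (>= 2 groups, each n >= 2).
#' @param control control group name (required for Dunnett).
#' @param method `"anova_dunnett"` or `"anova_tukey"`.
#' @return list with `f_statistic`, `df_between`, `df_within`, `f_p_value`
#'   and `contrasts` (`data.frame`: `contrast`, `estimate`, `p_adj`,
#'   `method`).
#' @export
compareMany <- function(groups, control = NULL,
                        method = c("anova_dunnett", "anova_tukey")) {
  method <- match.arg(method)
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs n >= 2")
  if (method == "anova_dunnett") {
    if (is.null(control)) stop("Dunnett comparisons require a control group")
    if (!control %in% names(groups))
      stop("control '", control, "' is not a group name")
  }
  lev <- names(groups)
  if (!is.null(control)) lev <- c(control, setdiff(lev, control))
  dat <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 1L)),
               levels = lev))
  fit <- stats::aov(y ~ g, data = dat)
  an <- stats::anova(fit)
  fstat <- an[["F value"]][1]
  if (is.nan(fstat)) fstat <- 0  # zero between- and within-group variance
  fp <- an[["Pr(>F)"]][1]
  if (is.nan(fp)) fp <- 1

  if (method == "anova_tukey") {
    tk <- stats::TukeyHSD(fit)$g
    contrasts <- data.frame(contrast = rownames(tk),
                            estimate = tk[, "diff"],
                            p_adj = tk[, "p adj"],
                            method = method, row.names = NULL)
  } else {
    # freeze the RNG locally: multcomp's multivariate-t integration is
    # quasi-random
    hadSeed <- exists(".Random.seed", envir = globalenv())
    if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(190651L)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    contrasts <- data.frame(contrast = names(sm$test$coefficients),
                            estimate = unname(sm$test$coefficients),
                            p_adj = pmin(1, unname(as.vector(sm$test$pvalues))),
                            method = method, row.names = NULL)
  }
  list(f_statistic = fstat, df_between = an$Df[1], df_within = an$Df[2],
       f_p_value = fp, contrasts = contrasts)
}

#' Summarize a full fed-vs-starved experiment
#'
#' For every genotype (each with a fed and a starved arm): sleep loss over
#' the configured ST window (default ST12-ST24), the bout-metric
#' decomposition before and after the first LD shift, the per-genotype
#' fed-vs-starved t test on total sleep, and — with more than one genotype
#' — ANOVA with post-hoc contrasts on starved-arm total sleep.
#' Deterministic given its inputs.
#'
#' @param seriesByGenotype named list; each element a list with `fed` and
#'   `starved` lists of [ActivitySeries-class].
#' @param design an [ExperimentDesign-class] with starvation set.
#' @param stFrom,stTo loss window in starvation-time hours.
#' @param control control genotype for Dunnett; with `NULL`, Tukey is used
#'   when several genotypes are present.
#' @param thresholdMin sleep threshold, minutes.
#' @param twoSample two-sample method, `"student_t"` or `"welch_t"`.
#' @return list of data.frames: `loss`, `bout_decomposition`,
#'   `two_sample`, and (optionally) `posthoc`.
#' @export
summarizeExperiment <- function(seriesByGenotype, design, stFrom = 12,
                                stTo = 24, control = NULL,
                                thresholdMin = 5L,
                                twoSample = "student_t") {
  stopifnot(is(design, "ExperimentDesign"))
  win <- stWindow(design, stFrom, stTo)
  shift <- firstLdShift(design)
  shiftMin <- starvationStartMin(design) + shift$stHours * 60
  nRec <- design@nDays * 1440
  preWin <- c(max(0, shiftMin - 720), shiftMin)
  postWin <- c(shiftMin, min(nRec, shiftMin + 720))

  lossRows <- list(); boutRows <- list(); ttRows <- list()
  starvedTotals <- list()
  for (g in names(seriesByGenotype)) {
    arms <- seriesByGenotype[[g]]
    if (is.null(arms$fed) || is.null(arms$starved))
      stop("genotype '", g, "' is missing a fed or starved arm")
    fed <- summarizeCohort(arms$fed, win, "fed", g, thresholdMin)
    stv <- summarizeCohort(arms$starved, win, "starved", g, thresholdMin)
    lossRows[[g]] <- sleepLossPct(fed, stv)
    starvedTotals[[g]] <- stv@metrics$total_sleep_min
    tt <- compareTwo(fed@metrics$total_sleep_min,
                     stv@metrics$total_sleep_min, method = twoSample)
    tt$contrast <- paste0(g, ": fed-starved")
    tt$genotype <- g
    ttRows[[g]] <- tt
    for (arm in c("fed", "starved")) {
      sl <- arms[[arm]]
      for (phase in c("pre_shift", "post_shift")) {
        w <- if (phase == "pre_shift") preWin else postWin
        mm <- do.call(rbind, lapply(sl, function(s)
          boutMetrics(scoreSleep(s, thresholdMin = thresholdMin), w)))
        boutRows[[length(boutRows) + 1L]] <- data.frame(
          genotype = g, arm = arm, phase = phase, n = nrow(mm),
          mean_total_sleep_min = mean(mm$total_sleep_min),
          mean_bout_number = mean(mm$bout_number),
          mean_bout_duration_min =
            mean(mm$mean_bout_duration_min, na.rm = TRUE))
      }
    }
  }
  res <- list(loss = do.call(rbind, c(lossRows, list(make.row.names = FALSE))),
              bout_decomposition = do.call(rbind, boutRows),
              two_sample = do.call(rbind, c(ttRows, list(make.row.names = FALSE))))
  if (length(seriesByGenotype) > 1L) {
    method <- if (is.null(control)) "anova_tukey" else "anova_dunnett"
    ph <- compareMany(starvedTotals, control = control, method = method)
    res$posthoc <- cbind(ph$contrasts,
                         f_statistic = ph$f_statistic,
                         f_p_value = ph$f_p_value)
  }
  res
}
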