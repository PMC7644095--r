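# Run configuration and the command-level entry points behind the
# `flysleep` script. Each command validates its config, writes its tabular
# artifacts as TSV (plot data is always emitted as numbers, never pixels),
# and drops a manifest with the config hash, seed and package version so
# identical configs give byte-identical outputs.

#' Read and validate a run configuration
#'
#' YAML (or JSON) with a `design` block (`lights_on`, `light_hours`,
#' `starvation_start_zt`, `starvation_day`, `n_days`), optional `analysis`
#' block (`sleep_threshold_min`, `bin_min`, `st_from`, `st_to`, `control`,
#' `two_sample`), optional `sholl` block (`n_rings`, `ring_spacing_um`,
#' `cone_full_angle_deg`), optional `sim` block (sleep/arbor generator
#' fields), `seed`, and input lists (`monitors`, `skeletons`).
#'
#' @param path config file.
#' @return validated list with parsed `design`, `sholl` and `params`
#'   objects alongside the raw fields.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  d <- cfg$design
  if (is.null(d)) stop("config is missing the 'design' block")
  design <- experimentDesign(
    lightsOnClock = if (is.null(d$lights_on)) "06:30" else d$lights_on,
    lightHours = if (is.null(d$light_hours)) 12 else d$light_hours,
    starvationStartZt =
      if (is.null(d$starvation_start_zt)) NA_real_ else d$starvation_start_zt,
    starvationDay = if (is.null(d$starvation_day)) 2L else d$starvation_day,
    nDays = if (is.null(d$n_days)) 3L else d$n_days)
  sh <- cfg$sholl
  sholl <- shollConfig(
    nRings = if (is.null(sh$n_rings)) 15L else sh$n_rings,
    ringSpacingUm = if (is.null(sh$ring_spacing_um)) 10 else sh$ring_spacing_um,
    coneFullAngleDeg =
      if (is.null(sh$cone_full_angle_deg)) 15 else sh$cone_full_angle_deg)
  a <- cfg$analysis
  analysis <- list(
    sleep_threshold_min =
      if (is.null(a$sleep_threshold_min)) 5L else a$sleep_threshold_min,
    bin_min = if (is.null(a$bin_min)) 30L else a$bin_min,
    st_from = if (is.null(a$st_from)) 12 else a$st_from,
    st_to = if (is.null(a$st_to)) 24 else a$st_to,
    control = a$control,
    two_sample = if (is.null(a$two_sample)) "student_t" else a$two_sample)
  s <- cfg$sim
  params <- sleepSimParams(
    pInitLight = if (is.null(s$p_init_light)) 0.04 else s$p_init_light,
    pInitDark = if (is.null(s$p_init_dark)) 0.10 else s$p_init_dark,
    boutLenMeanLight =
      if (is.null(s$bout_len_mean_light)) 25 else s$bout_len_mean_light,
    boutLenMeanDark =
      if (is.null(s$bout_len_mean_dark)) 40 else s$bout_len_mean_dark,
    starvationInitMultiplier =
      if (is.null(s$starvation_init_multiplier)) 0.5
      else s$starvation_init_multiplier,
    activeCountRate =
      if (is.null(s$active_count_rate)) 2 else s$active_count_rate)
  arbor <- arborSimParams(
    nBranches = if (is.null(s$n_branches)) 8L else s$n_branches,
    spreadSigmaDeg =
      if (is.null(s$spread_sigma_deg)) 15 else s$spread_sigma_deg)
  for (m in cfg$monitors)
    if (!is.null(m$path) && !file.exists(m$path))
      stop("monitor file does not exist: ", m$path)
  for (k in cfg$skeletons)
    if (!is.null(k$path) && !file.exists(k$path))
      stop("skeleton file does not exist: ", k$path)
  list(design = design, sholl = sholl, analysis = analysis, params = params,
       arbor = arbor, monitors = cfg$monitors, skeletons = cfg$skeletons,
       n_per_arm = if (is.null(cfg$n_per_arm)) 32L else cfg$n_per_arm,
       seed = if (is.null(cfg$seed)) 1L else cfg$seed,
       out_dir = if (is.null(cfg$out_dir)) "." else cfg$out_dir)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.writeManifest <- function(cfg, outDir, command) {
  canon <- tempfile()
  jsonlite::write_json(
    list(command = command, seed = cfg$seed,
         analysis = cfg$analysis,
         design = list(lights_on = cfg$design@lightsOnClock,
                       light_hours = cfg$design@lightHours,
                       starvation_start_zt = cfg$design@starvationStartZt,
                       starvation_day = cfg$design@starvationDay,
                       n_days = cfg$design@nDays)),
    canon, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    command = command,
    config_hash = unname(tools::md5sum(canon)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("FlySleepDI")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  unlink(canon)
  invisible(manifest)
}

.loadSeriesByGenotype <- function(cfg) {
  out <- list()
  for (m in cfg$monitors) {
    tab <- readMonitorFile(m$path,
                           dialect = if (is.null(m$dialect)) "dam"
                                     else m$dialect)
    chans <- if (is.null(m$channels)) 1:32 else unlist(m$channels)
    genotype <- if (is.null(m$genotype)) "wt" else m$genotype
    arm <- if (is.null(m$arm)) "fed" else m$arm
    sl <- lapply(chans, function(ch) sliceChannel(tab, ch))
    if (is.null(out[[genotype]])) out[[genotype]] <- list()
    out[[genotype]][[arm]] <- c(out[[genotype]][[arm]], sl)
  }
  out
}

#' Sleep analysis command
#'
#' Scores every configured monitor channel, then writes per-fly metrics,
#' the per-genotype loss table, the comparison table, and per-bin sleep
#' profiles, plus a manifest. Exit-status convention of the wrapper
#' script: 0 success, 1 validation error.
#'
#' @param cfg parsed config from [readRunConfig()] (or an equivalent list).
#' @param outDir output directory (created if needed).
#' @return (invisibly) named list of artifact paths.
#' @export
cmdSleep <- function(cfg, outDir = cfg$out_dir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  byGeno <- .loadSeriesByGenotype(cfg)
  if (!length(byGeno)) stop("no monitors configured")
  res <- summarizeExperiment(byGeno, cfg$design,
                             stFrom = cfg$analysis$st_from,
                             stTo = cfg$analysis$st_to,
                             control = cfg$analysis$control,
                             thresholdMin = cfg$analysis$sleep_threshold_min,
                             twoSample = cfg$analysis$two_sample)
  win <- stWindow(cfg$design, cfg$analysis$st_from, cfg$analysis$st_to)
  perFly <- do.call(rbind, lapply(names(byGeno), function(g) {
    do.call(rbind, lapply(c("fed", "starved"), function(arm) {
      cs <- summarizeCohort(byGeno[[g]][[arm]], win, arm, g,
                            cfg$analysis$sleep_threshold_min)
      cbind(genotype = g, arm = arm, cs@metrics,
            window_from_min = win[1], window_to_min = win[2])
    }))
  }))
  profile <- do.call(rbind, lapply(names(byGeno), function(g) {
    do.call(rbind, lapply(c("fed", "starved"), function(arm) {
      profs <- lapply(byGeno[[g]][[arm]], function(s)
        sleepProfile(scoreSleep(s, cfg$analysis$sleep_threshold_min),
                     cfg$design, binMin = cfg$analysis$bin_min))
      base <- profs[[1]][, c("bin_start_min", "zt")]
      vals <- rowMeans(sapply(profs, `[[`, "minutes_asleep"))
      cbind(genotype = g, arm = arm, base, mean_minutes_asleep = vals)
    }))
  }))
  paths <- list(
    per_fly = .writeTsv(perFly, file.path(outDir, "per_fly_metrics.tsv")),
    loss = .writeTsv(res$loss, file.path(outDir, "loss_table.tsv")),
    bouts = .writeTsv(res$bout_decomposition,
                      file.path(outDir, "bout_decomposition.tsv")),
    comparisons = .writeTsv(
      if (is.null(res$posthoc)) res$two_sample
      else merge(res$two_sample, res$posthoc, all = TRUE),
      file.path(outDir, "comparison_table.tsv")),
    profile = .writeTsv(profile, file.path(outDir, "sleep_profile.tsv")))
  .writeManifest(cfg, outDir, "sleep")
  invisible(paths)
}

#' Defasciculation-index command
#'
#' Computes DI for every configured skeleton file; per-file failures are
#' flagged rows, the batch continues. Writes the per-hemisphere DI table
#' and the per-group summary. Wrapper exit status: 2 when some rows
#' failed, 1 when all did.
#'
#' @inheritParams cmdSleep
#' @return (invisibly) list of artifact paths plus `n_failed`.
#' @export
cmdDefasc <- function(cfg, outDir = cfg$out_dir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!length(cfg$skeletons)) stop("no skeletons configured")
  skels <- list(); groups <- character()
  for (k in cfg$skeletons) {
    lab <- if (is.null(k$label))
      tools::file_path_sans_ext(basename(k$path)) else k$label
    skels[[lab]] <- tryCatch(
      readSkeleton(k$path,
                   dialect = if (is.null(k$dialect)) "swc" else k$dialect,
                   root = if (is.null(k$root)) NULL else unlist(k$root)),
      error = function(e) e)
    groups <- c(groups, if (is.null(k$group)) "all" else k$group)
  }
  bad <- vapply(skels, is, logical(1), "error")
  rows <- diBatch(skels[!bad], cfg$sholl, groups = groups[!bad])
  if (any(bad)) {
    failRows <- data.frame(label = names(skels)[bad],
                           group = groups[bad], total = NA_integer_,
                           in_cone = NA_integer_, di = NA_real_,
                           cone_center_deg = NA_real_,
                           flag = vapply(skels[bad], conditionMessage,
                                         character(1)))
    rows$rows <- rbind(rows$rows, failRows)
  }
  paths <- list(
    di = .writeTsv(rows$rows, file.path(outDir, "di_table.tsv")),
    summary = .writeTsv(rows$summary, file.path(outDir, "di_summary.tsv")),
    n_failed = sum(is.na(rows$rows$di)))
  .writeManifest(cfg, outDir, "defasc")
  invisible(paths)
}

#' Simulation command
#'
#' Generates a two-arm synthetic experiment and a set of arbors, writes
#' them through the real DAM and SWC writers (fed arm in Monitor1, starved
#' in Monitor2), and drops a ground-truth JSON with the closed-form
#' expected loss, stationary fractions, and arbor spread.
#'
#' @inheritParams cmdSleep
#' @param nArbors arbors to generate.
#' @return (invisibly) list of artifact paths.
#' @export
cmdSimulate <- function(cfg, outDir = cfg$out_dir, nArbors = 8L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  n <- cfg$n_per_arm
  if (n > 32L) stop("n_per_arm must be <= 32 (one monitor per arm)")
  cohort <- simulateCohort(cfg$params, cfg$design, n, cfg$seed)
  fedTab <- monitorTableFromSeries(cohort$fed, monitorId = "Monitor1")
  stvTab <- monitorTableFromSeries(cohort$starved, monitorId = "Monitor2")
  p1 <- file.path(outDir, "Monitor1.txt")
  p2 <- file.path(outDir, "Monitor2.txt")
  writeMonitorFile(fedTab, p1, "dam")
  writeMonitorFile(stvTab, p2, "dam")
  arborPaths <- vapply(seq_len(nArbors), function(i) {
    sk <- generateArbor(cfg$arbor, seed = cfg$seed + 5000L + i)
    p <- file.path(outDir, sprintf("arbor_%03d.swc", i))
    writeSkeleton(sk, p, "swc")
    p
  }, character(1))
  exp <- expectedSleepLoss(cfg$params, cfg$design,
                           cfg$analysis$st_from, cfg$analysis$st_to)
  jsonlite::write_json(
    list(expected_loss_pct = exp$loss_pct,
         fed_stationary_fraction = exp$fed_fraction,
         starved_stationary_fraction = exp$starved_fraction,
         arbor_spread_sigma_deg = cfg$arbor@spreadSigmaDeg,
         n_per_arm = n, seed = cfg$seed),
    file.path(outDir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  .writeManifest(cfg, outDir, "simulate")
  invisible(list(monitors = c(p1, p2), arbors = arborPaths,
                 ground_truth = file.path(outDir, "ground_truth.json")))
}
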