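#' Simulate a cohort of electrodes to disk
#'
#' Writes, per electrode, the oxide-reduction sweep, the 6-cycle stripping
#' sweep, and the fluorescence tables in exactly the formats the analysis
#' side reads, plus `manifest.json` mapping electrode_id to the planted and
#' realized truth and `run_config.json` ready for [analyze_cohort()].
#'
#' @param config A [ground_truth()] configuration (fields may be ranges).
#' @param n_electrodes Number of electrodes.
#' @param outdir Output directory (created if missing).
#' @param group Grouping label stored with every electrode (e.g. the
#'   stripping medium).
#' @return Path of the written run config, invisibly.
#' @export
simulate_cohort <- function(config, n_electrodes, outdir, group = "default") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gts <- generate_ensemble(config, n_electrodes)
  manifest <- list()
  electrodes <- list()
  for (i in seq_along(gts)) {
    gt <- gts[[i]]
    id <- sprintf("E%03d", i)
    sim <- simulate_voltammograms(gt)
    flu <- simulate_fluorescence(gt, truth = sim$truth)
    f_ox <- file.path(outdir, paste0(id, "_oxide.csv"))
    f_st <- file.path(outdir, paste0(id, "_stripping.csv"))
    f_std <- file.path(outdir, paste0(id, "_standards.csv"))
    f_smp <- file.path(outdir, paste0(id, "_sample.csv"))
    write_voltammogram(sim$oxide, f_ox)
    write_voltammogram(sim$stripping, f_st)
    utils::write.csv(flu$standards, f_std, row.names = FALSE)
    utils::write.csv(data.frame(electrode_id = id,
                                intensity = flu$sample$intensity,
                                volume_uL = gt$volume * 1e6),
                     f_smp, row.names = FALSE)
    tr <- sim$truth
    manifest[[id]] <- list(
      seed = gt$seed, d_mean = tr$d_mean, d_sd = tr$d_sd, n_np = tr$n_np,
      d_cw = tr$d_cw, s_total = tr$s_total, q_strip = tr$q_strip,
      q_ox = tr$q_ox, enzyme_count = tr$enzyme_count,
      per_np_planted = tr$enzyme_count / tr$n_np,
      electrode_diameter = gt$electrode_diameter, group = group)
    electrodes[[id]] <- list(oxide = basename(f_ox),
                             stripping = basename(f_st),
                             standards = basename(f_std),
                             sample = basename(f_smp), group = group)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_cfg <- list(
    electrodes = electrodes,
    constants = list(k_ox = stripping_constants()$k_ox, n_eff = 1.9, x = 2),
    windows = list(oxide = c(0.9, 1.35), stripping = c(1.1, 1.5)),
    baseline_method = "linear_anchors",
    electrode_diameter = config$electrode_diameter,
    seed = config$seed)
  cfg_path <- file.path(outdir, "run_config.json")
  jsonlite::write_json(run_cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(cfg_path)
}

#' Load a run configuration
#' @param path Path to a `run_config.json` written by [simulate_cohort()] or
#'   by hand (keys: `electrodes`, `constants`, `windows`,
#'   `baseline_method`, `electrode_diameter`, `seed`).
#' @return A `run_config` list; file paths are resolved relative to the
#'   config's directory and checked for existence.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg$dir <- dirname(normalizePath(path))
  for (id in names(cfg$electrodes)) {
    el <- cfg$electrodes[[id]]
    for (key in c("oxide", "stripping", "standards", "sample")) {
      if (!is.null(el[[key]])) {
        p <- file.path(cfg$dir, el[[key]])
        if (!file.exists(p)) {
          stop("missing input for ", id, ": ", p, call. = FALSE)
        }
        cfg$electrodes[[id]][[key]] <- p
      }
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Analyze one electrode: charges, nanoparticle estimate, enzyme report
#'
#' Executes the stages in order: read both voltammograms, shift to NHE,
#' baseline-correct and integrate the cathodic oxide-reduction and anodic
#' stripping peaks, invert the charges to the nanoparticle estimate, then
#' (when fluorescence inputs exist) fit the calibration, inverse-predict the
#' concentration and build the enzyme report.  Every intermediate is kept in
#' the returned report; a stage failure is recorded in `$errors` and later
#' stages are skipped rather than aborting the run.
#'
#' @param config A [read_run_config()] result (or its path).
#' @param electrode_id Electrode key in the config.
#' @return An `electrode_report`: `id`, `charges` (oxide/stripping
#'   [integrate_charge()] results), `np` ([estimate_np()]), `enzyme`
#'   ([per_np_and_footprint()] or `NULL`), `calibration`, `group`, `errors`,
#'   `flags`.
#' @export
analyze_electrode <- function(config, electrode_id) {
  if (is.character(config)) config <- read_run_config(config)
  el <- config$electrodes[[electrode_id]]
  if (is.null(el)) stop("unknown electrode: ", electrode_id, call. = FALSE)
  consts <- stripping_constants(
    k_ox = config$constants$k_ox %||% 489e-6,
    n_eff = config$constants$n_eff %||% 1.9,
    x = config$constants$x %||% 2)
  bl <- config$baseline_method %||% "linear_anchors"
  w_ox <- peak_window(config$windows$oxide[1] %||% 0.9,
                      config$windows$oxide[2] %||% 1.35, "cathodic")
  w_st <- peak_window(config$windows$stripping[1] %||% 1.1,
                      config$windows$stripping[2] %||% 1.5, "anodic")
  rep <- structure(list(id = electrode_id, charges = list(), np = NULL,
                        enzyme = NULL, calibration = NULL,
                        group = el$group %||% "default",
                        errors = character(), flags = character()),
                   class = "electrode_report")
  q <- tryCatch({
    v_ox <- to_nhe(read_voltammogram(el$oxide, "two_column_csv"))
    v_st <- to_nhe(read_voltammogram(el$stripping, "two_column_csv"))
    list(ox = integrate_charge(v_ox, w_ox, bl),
         st = integrate_charge(v_st, w_st, bl))
  }, error = function(e) conditionMessage(e))
  if (is.character(q)) {
    rep$errors <- c(rep$errors, paste0("voltammetry: ", q))
    return(rep)
  }
  rep$charges <- list(oxide = q$ox, stripping = q$st)
  np <- tryCatch(
    estimate_np(q$st$q, q$ox$q, config$electrode_diameter %||% 3, consts),
    error = function(e) conditionMessage(e))
  if (is.character(np)) {
    rep$errors <- c(rep$errors, paste0("np_estimate: ", np))
    return(rep)
  }
  rep$np <- np
  if (is.null(el$standards) || is.null(el$sample)) {
    rep$flags <- c(rep$flags, "no_fluorescence_input")
    return(rep)
  }
  enz <- tryCatch({
    std <- utils::read.csv(el$standards)
    smp <- utils::read.csv(el$sample)
    curve <- fit_calibration(std)
    cc <- concentration_from_intensity(curve, smp$intensity[1])
    vol <- if ("volume_uL" %in% names(smp)) smp$volume_uL[1] * 1e-6 else 200e-6
    count <- enzyme_count(cc$conc, vol)
    list(curve = curve,
         report = per_np_and_footprint(count, np, conc = cc$conc,
                                       volume = vol, flags = cc$flags))
  }, error = function(e) conditionMessage(e))
  if (is.character(enz)) {
    rep$errors <- c(rep$errors, paste0("fluorimetry: ", enz))
    return(rep)
  }
  rep$calibration <- enz$curve
  rep$enzyme <- enz$report
  rep
}

#' Analyze every electrode of a run configuration
#'
#' @param config Path to a run config, or a [read_run_config()] result.
#' @return List of `electrode_report`s, named by electrode id.
#' @export
analyze_cohort <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  ids <- names(config$electrodes)
  stats::setNames(lapply(ids, function(id) analyze_electrode(config, id)), ids)
}

report_metrics <- function(rep) {
  np <- rep$np
  data.frame(
    id = rep$id, group = rep$group,
    d = if (is.null(np)) NA_real_ else np$d,
    n_np = if (is.null(np)) NA_real_ else np$n_np,
    s_total = if (is.null(np)) NA_real_ else np$s_total,
    coverage = if (is.null(np)) NA_real_ else np$coverage,
    per_np = if (is.null(rep$enzyme)) NA_real_ else rep$enzyme$per_np,
    footprint = if (is.null(rep$enzyme)) NA_real_ else rep$enzyme$footprint,
    ok = length(rep$errors) == 0)
}

#' Cohort summary: unweighted mean and SD per metric per group
#'
#' Aggregates per-electrode estimates the way replicate-electrode tables are
#' conventionally reported: estimate each electrode individually, then take
#' the unweighted mean and sample SD across electrodes.  Electrodes that
#' failed any stage are excluded and listed in the `excluded` attribute —
#' the cohort never silently shrinks.
#'
#' @param reports List of `electrode_report`s from [analyze_cohort()].
#' @param group_by Ignored unless `"group"` (the stored per-electrode label).
#' @return A data.frame with one row per (group, metric): columns `group`,
#'   `metric` (d, n_np, s_total, coverage, per_np, footprint), `mean`, `sd`
#'   (`NA` when n = 1), `n`.
#' @export
summarize_cohort <- function(reports, group_by = "group") {
  if (length(reports) == 0) {
    warning("empty cohort", call. = FALSE)
    return(data.frame(group = character(), metric = character(),
                      mean = numeric(), sd = numeric(), n = integer()))
  }
  tab <- do.call(rbind, lapply(reports, report_metrics))
  excluded <- tab$id[!tab$ok]
  tab <- tab[tab$ok, , drop = FALSE]
  metrics <- c("d", "n_np", "s_total", "coverage", "per_np", "footprint")
  rows <- list()
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, , drop = FALSE]
    for (m in metrics) {
      x <- sub[[m]][is.finite(sub[[m]])]
      n <- length(x)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m,
        mean = if (n > 0) mean(x) else NA_real_,
        sd = if (n > 1) stats::sd(x) else NA_real_, n = n)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Write an analyzed cohort to a report directory
#'
#' Emits `per_electrode.csv` (one row per electrode with all headline
#' metrics), `cohort_summary.csv`, and `run_manifest.json` echoing the
#' configuration for reproducibility.
#'
#' @param reports List from [analyze_cohort()].
#' @param config The `run_config` used.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_reports <- function(reports, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(reports, report_metrics))
  utils::write.csv(tab, file.path(outdir, "per_electrode.csv"),
                   row.names = FALSE)
  summ <- summarize_cohort(reports)
  utils::write.csv(summ, file.path(outdir, "cohort_summary.csv"),
                   row.names = FALSE)
  errs <- lapply(reports, function(r) r$errors)
  manifest <- list(
    constants = config$constants, windows = config$windows,
    baseline_method = config$baseline_method,
    electrode_diameter = config$electrode_diameter,
    excluded = attr(summ, "excluded"),
    errors = errs[vapply(errs, length, integer(1)) > 0])
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Simulate, analyze and compare to the planted truth
#'
#' The recovery harness: simulates a cohort, runs the full analysis on the
#' written files, and joins the estimates to the truth manifest.
#'
#' @param config A [ground_truth()] configuration.
#' @param n_electrodes Number of electrodes.
#' @param outdir Working directory for the simulated files.
#' @return A data.frame with per-electrode planted truth (`d_mean`, `d_cw`,
#'   `n_np_true`, `per_np_planted`), estimates (`d_hat`, `n_np_hat`,
#'   `per_np_hat`, `footprint_hat`, `s_total_hat`) and relative errors
#'   vs the charge-weighted bookkeeping truth (`rel_d`, `rel_n`).
#' @export
recover_run <- function(config, n_electrodes, outdir = tempfile("recover")) {
  cfg_path <- simulate_cohort(config, n_electrodes, outdir)
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                                  simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  reports <- analyze_cohort(cfg_path)
  rows <- lapply(names(reports), function(id) {
    m <- manifest[[id]]
    r <- reports[[id]]
    n_cw <- m$s_total / (2 * pi * nm_to_cm(m$d_cw / 2)^2)
    data.frame(
      id = id, d_mean = m$d_mean, d_cw = m$d_cw, n_np_true = m$n_np,
      n_cw = n_cw, per_np_planted = m$per_np_planted,
      d_hat = if (is.null(r$np)) NA_real_ else r$np$d,
      n_np_hat = if (is.null(r$np)) NA_real_ else r$np$n_np,
      s_total_hat = if (is.null(r$np)) NA_real_ else r$np$s_total,
      per_np_hat = if (is.null(r$enzyme)) NA_real_ else r$enzyme$per_np,
      footprint_hat = if (is.null(r$enzyme)) NA_real_ else r$enzyme$footprint)
  })
  out <- do.call(rbind, rows)
  out$rel_d <- abs(out$d_hat - out$d_cw) / out$d_cw
  out$rel_n <- abs(out$n_np_hat - out$n_cw) / out$n_cw
  out
}
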