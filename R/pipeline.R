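#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file with the same
#' structure) describing one reproducible experiment: the connectome
#' source (a file or a synthetic-generator spec), a cohort preset,
#' model parameters, the stages to run, the stimulation and EZ/PZ
#' specification, a seed and an output directory. Field-level problems
#' are reported together.
#'
#' @param config named list or path to a YAML file.
#' @return the validated (and default-filled) configuration, invisibly
#'   classed `runConfig`.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  errs <- character(0)
  preset_name <- config$preset %||% "healthy"
  if (!preset_name %in% c("healthy", "patient"))
    errs <- c(errs, "preset: must be 'healthy' or 'patient'")
  preset <- networkPreset(if (preset_name %in% c("healthy", "patient"))
    preset_name else "healthy")
  if (is.null(config$connectome)) config$connectome <- list()
  cn <- config$connectome
  if (!is.null(cn$file) && !file.exists(cn$file))
    errs <- c(errs, paste0("connectome.file: not found (", cn$file, ")"))
  if (!is.null(config$ezpz_file) && !file.exists(config$ezpz_file))
    errs <- c(errs, paste0("ezpz_file: not found (", config$ezpz_file, ")"))
  stages_ok <- c("synth", "metrics", "sweep", "stimulate", "spectrogram",
                 "scan", "evaluate")
  config$stages <- config$stages %||% c("synth", "metrics", "stimulate",
                                        "evaluate")
  bad <- setdiff(config$stages, stages_ok)
  if (length(bad))
    errs <- c(errs, paste0("stages: unknown stage(s) ",
                           paste(bad, collapse = ", ")))
  config$seed <- as.integer(config$seed %||% 1L)
  model <- config$model %||% list()
  config$model <- list(
    eta_bar = model$eta_bar %||% preset$eta_bar,
    delta = model$delta %||% preset$delta,
    tau_m = model$tau_m %||% preset$tau_m,
    sigma = model$sigma %||% preset$sigma,
    dt = model$dt %||% 0.01)
  stim <- config$stimulus %||% list()
  config$stimulus <- list(amplitude = stim$amplitude %||% preset$I_S,
                          duration = stim$duration %||% preset$t_I)
  config$preset <- preset_name
  config$n_regions <- cn$n_regions %||% preset$n_regions
  if (length(errs))
    stop("invalid run configuration:\n  ",
         paste(errs, collapse = "\n  "))
  invisible(structure(config, class = "runConfig"))
}

#' Run a configured experiment pipeline
#'
#' Executes the requested stages on one connectome and writes all
#' outputs (CSV tables, JSON specs) plus a JSON manifest recording the
#' full configuration, seed, package version and output checksums, so a
#' run can be reproduced bit-identically from its output directory.
#'
#' Stages: `"synth"` (generate or load the connectome and EZ/PZ spec),
#' `"metrics"` (per-region graph metrics), `"sweep"` (up/down
#' bifurcation sweep), `"stimulate"` (EZ stimulation + recruitment
#' detection), `"spectrogram"` (STFT of the mean voltage of the
#' stimulation run), `"scan"` (per-region threshold map), `"evaluate"`
#' (recruitment report against the EZ/PZ spec).
#'
#' @param config a list, `runConfig` or YAML path (see
#'   [validateRunConfig()]).
#' @param out_dir output directory (created if missing).
#' @param ... stage tuning overrides: `sweep_args`, `scan_args`,
#'   `stim_args` lists passed to the respective protocol functions.
#' @return list with the in-memory stage results, invisibly.
#' @export
runPipeline <- function(config, out_dir, ...) {
  config <- validateRunConfig(config)
  dots <- list(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)

  conn <- if (!is.null(config$connectome$file)) {
    normalizeConnectome(loadConnectome(config$connectome$file))
  } else {
    syn <- config$connectome
    synthConnectome(n_regions = config$n_regions,
                    density = syn$density %||% 0.5,
                    lognormal_mu = syn$lognormal_mu %||% -3,
                    lognormal_sigma = syn$lognormal_sigma %||% 1,
                    symmetric = syn$symmetric %||% TRUE,
                    hub_bias = syn$hub_bias %||% 0,
                    seed = config$seed)
  }
  res$connectome <- conn
  spec <- if (!is.null(config$ezpz_file)) readEzPz(config$ezpz_file)
          else synthEzPz(conn, ez_size = config$ezpz$ez_size %||% 1,
                         pz_size = config$ezpz$pz_size %||% 3,
                         seed = config$seed + 1L)
  res$ezpz <- spec

  m <- config$model
  params <- neuralMassParams(conn$n_regions, eta_bar = m$eta_bar,
                             delta = m$delta, tau_m = m$tau_m)
  cpl <- buildCoupling(conn, sigma = m$sigma)

  if ("synth" %in% config$stages) {
    saveConnectome(conn, file.path(out_dir, "connectome.txt"))
    writeEzPz(spec, file.path(out_dir, "ezpz.json"))
  }
  if ("metrics" %in% config$stages) {
    res$metrics <- metricTable(conn)
    utils::write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  if ("sweep" %in% config$stages) {
    res$sweep <- do.call(adiabaticSweep,
                         c(list(cpl, params), dots$sweep_args))
    sw <- data.frame(eta = res$sweep$up$eta,
                     up = res$sweep$up$mean_rate,
                     down = rev(res$sweep$down$mean_rate))
    utils::write.csv(sw, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
  }
  traj <- NULL
  if (any(c("stimulate", "spectrogram", "evaluate") %in% config$stages)) {
    stim <- stimulusProtocol(spec$ez,
                             amplitude = config$stimulus$amplitude,
                             duration = config$stimulus$duration)
    stim_args <- c(list(cpl, params, stim, dt = m$dt), dots$stim_args)
    traj <- do.call(runStimulation, stim_args)
    res$recruitment <- detectRecruitments(traj,
                                          J_self = m$sigma * cpl$intra)
    utils::write.csv(
      data.frame(area = seq_along(res$recruitment$recruit_time),
                 recruit_time = res$recruitment$recruit_time),
      file.path(out_dir, "recruitment.csv"), row.names = FALSE)
  }
  if ("spectrogram" %in% config$stages) {
    rec_dt <- diff(traj$times[1:2])
    res$spectrogram <- stSpectrogram(rowMeans(traj$v),
                                     fs = 1000 / rec_dt)
    utils::write.csv(spectrogramTable(res$spectrogram),
                     file.path(out_dir, "spectrogram.csv"),
                     row.names = FALSE)
  }
  if ("scan" %in% config$stages) {
    scan_args <- c(list(cpl, params), dots$scan_args)
    res$threshold_map <- do.call(thresholdMap, scan_args)
    utils::write.csv(
      data.frame(area = res$threshold_map$areas,
                 eta_asy = res$threshold_map$eta_asy,
                 eta_gen = res$threshold_map$eta_gen),
      file.path(out_dir, "thresholds.csv"), row.names = FALSE)
  }
  if ("evaluate" %in% config$stages) {
    res$report <- recruitmentReport(res$recruitment, spec)
    jsonlite::write_json(
      list(classification = res$report$classification,
           time_stats = res$report$time_stats,
           pz_clin = res$report$pz_clin[c("hits", "fraction")],
           pz_seeg = res$report$pz_seeg[c("hits", "fraction")]),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "massnet",
    version = as.character(utils::packageVersion("massnet")),
    seed = config$seed,
    config = unclass(config),
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(file.path(out_dir, files)))), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
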