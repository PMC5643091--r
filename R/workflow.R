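# Orchestration: run configuration and end-to-end workflows.

#' Read or write a run configuration
#'
#' Run configurations are JSON with a `workflow` field (`optics`, `qc`,
#' `simulate`, or `conditioning`), an `rng_seed`, and per-module parameter
#' sections whose entries override the documented defaults.  Configurations
#' round-trip through serialisation unchanged.  A configuration stating
#' every standard parameter literally ships with the package:
#' `system.file("extdata", "default-config.json", package = "deepcalseq")`.
#'
#' @param path JSON file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A `run_config` (or plain named list).
#' @export
write_run_config <- function(config, path) {
  write_json_atomic(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  if (is.null(config$workflow) ||
      !config$workflow %in% c("optics", "qc", "simulate", "conditioning")) {
    stop_invalid("config$workflow must be one of optics, qc, simulate, conditioning")
  }
  config$rng_seed <- as.integer(config$rng_seed %||% 1L)
  structure(config, class = "run_config")
}

apply_overrides <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

#' Run an end-to-end workflow
#'
#' Executes one of the four workflows and writes its outputs plus a
#' manifest (`manifest.json`) recording the package version, seed, echoed
#' parameters, produced files and their record counts.  All outputs are
#' written atomically (write-then-rename), so a failed stage leaves no
#' partially written final file.  With a fixed seed, re-running a workflow
#' produces byte-identical outputs.
#'
#' Workflows:
#' \describe{
#'   \item{optics}{[optics_report()] from `config$optics` parameters.}
#'   \item{qc}{[simulate_volume()] (or a caller-supplied stack) followed by
#'     [depth_profiles()].}
#'   \item{simulate}{[simulate_session()]; writes the shared trace/event
#'     CSVs and ground-truth JSON.}
#'   \item{conditioning}{the full trace pipeline: [block_average()] ->
#'     [percentile_detrend()] -> [align_trials()] -> [trial_average()] ->
#'     [sequence_test()] -> [peak_time_histogram()] ->
#'     [split_half_peak_correlation()] (when enough pre-reward neurons),
#'     plus [behavior_summary()].  Inputs come from `config$traces` /
#'     `config$events` paths or are simulated in place from
#'     `config$session`.}
#' }
#'
#' @param config A `run_config` list (see [read_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
run_workflow <- function(config, out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$rng_seed
  outputs <- list()
  note <- character()
  add_output <- function(outputs, file, rows) {
    c(outputs, list(list(file = file, rows = rows)))
  }

  if (config$workflow == "optics") {
    cfg <- do.call(optical_config, as.list(config$optics %||% list()))
    rep <- optics_report(cfg)
    write_csv_atomic(rep, file.path(out_dir, "optics_report.csv"))
    outputs <- add_output(outputs, "optics_report.csv", nrow(rep))

  } else if (config$workflow == "qc") {
    vp <- do.call(volume_params,
                  apply_overrides(list(rng_seed = seed),
                                  as.list(config$volume %||% list())))
    vol <- simulate_volume(vp)
    qc <- config$qc %||% list()
    prof <- depth_profiles(vol$stack,
                           fraction = qc$fraction %||% 0.001,
                           r_min = qc$r_min %||% 6,
                           r_max = qc$r_max %||% 12,
                           sensitivity = qc$sensitivity %||% 0.5)
    write_csv_atomic(prof, file.path(out_dir, "depth_profile.csv"))
    write_csv_atomic(vol$truth$somata, file.path(out_dir, "somata_truth.csv"))
    outputs <- add_output(outputs, "depth_profile.csv", nrow(prof))
    outputs <- add_output(outputs, "somata_truth.csv",
                          nrow(vol$truth$somata))

  } else if (config$workflow == "simulate") {
    sp <- do.call(session_params,
                  apply_overrides(list(rng_seed = seed),
                                  as.list(config$session %||% list())))
    sim <- simulate_session(sp)
    write_atomic(file.path(out_dir, "traces.csv"),
                 function(p) write_traces(sim$traces, p))
    write_atomic(file.path(out_dir, "events.csv"),
                 function(p) write_events(sim$events, p))
    write_json_atomic(list(neurons = sim$truth$neurons,
                           events = sim$truth$events),
                      file.path(out_dir, "ground_truth.json"))
    outputs <- add_output(outputs, "traces.csv", nrow(sim$traces$values))
    outputs <- add_output(outputs, "events.csv",
                          length(sim$events$delivery_times) +
                            length(sim$events$lick_times))
    outputs <- add_output(outputs, "ground_truth.json",
                          nrow(sim$truth$neurons))

  } else { # conditioning
    if (!is.null(config$traces)) {
      if (!file.exists(config$traces) || !file.exists(config$events)) {
        stop_invalid("conditioning workflow: traces/events file not found")
      }
      traces <- read_traces(config$traces)
      events <- read_events(config$events)
    } else {
      sp <- do.call(session_params,
                    apply_overrides(list(rng_seed = seed),
                                    as.list(config$session %||% list())))
      sim <- simulate_session(sp)
      traces <- sim$traces
      events <- sim$events
    }
    pars <- config$conditioning %||% list()
    k <- pars$block %||% 3
    dff <- percentile_detrend(block_average(traces, k),
                              half_window = pars$half_window %||% 30,
                              percentile = pars$percentile %||% 8)
    tensor <- withCallingHandlers(
      align_trials(dff, events,
                   window = unlist(pars$window %||% c(-10, 10)),
                   response_window = pars$response_window %||% 2),
      warning = function(w) {
        note <<- c(note, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    n_dropped <- sum(tensor$trial_log$status != "included")
    if (n_dropped > 0) {
      note <- c(note, sprintf("%d deliveries excluded or dropped", n_dropped))
    }
    d <- dim(tensor$values)
    write_atomic(file.path(out_dir, "trial_tensor.rds"),
                 function(p) saveRDS(tensor, p))
    write_json_atomic(
      list(format = "rds", neurons = d[1], trials = d[2], frames = d[3],
           frame_rate = tensor$frame_rate,
           window_s = c(tensor$time_axis[1] - 0.5 / tensor$frame_rate,
                        tensor$time_axis[d[3]] + 0.5 / tensor$frame_rate),
           included_trials = tensor$included_trials),
      file.path(out_dir, "trial_tensor_header.json"))
    outputs <- add_output(outputs, "trial_tensor.rds", d[2])
    outputs <- add_output(outputs, "trial_tensor_header.json", 1L)

    st <- sequence_test(tensor, rng_seed = derive_seed(seed, 11),
                        ridge_frames = pars$ridge_frames %||% 12)
    hist <- peak_time_histogram(st$original)
    write_csv_atomic(st$original, file.path(out_dir, "ridge_original.csv"))
    write_csv_atomic(st$shuffled, file.path(out_dir, "ridge_shuffled.csv"))
    write_csv_atomic(hist, file.path(out_dir, "peak_histogram.csv"))
    write_csv_atomic(tensor$trial_log, file.path(out_dir, "trial_log.csv"))
    outputs <- add_output(outputs, "ridge_original.csv", nrow(st$original))
    outputs <- add_output(outputs, "ridge_shuffled.csv", nrow(st$shuffled))
    outputs <- add_output(outputs, "peak_histogram.csv", nrow(hist))
    outputs <- add_output(outputs, "trial_log.csv", nrow(tensor$trial_log))

    pre <- which(!is.na(st$original$peak_time) & st$original$peak_time < 0)
    nsub <- pars$n_subsample %||% 50
    if (length(pre) >= 2) {
      stab <- split_half_peak_correlation(
        subset_neurons(tensor, pre),
        n_subsample = min(nsub, length(pre)),
        n_reps = pars$n_reps %||% 1000,
        rng_seed = derive_seed(seed, 12))
      write_json_atomic(
        list(rng_seed = stab$rng_seed, n_subsample = stab$n_subsample,
             ci_low = stab$ci_low, ci_high = stab$ci_high,
             verdict_nonrandom = stab$verdict_nonrandom),
        file.path(out_dir, "stability.json"))
      write_csv_atomic(tibble::tibble(rep = seq_along(stab$correlations),
                                      r = stab$correlations),
                       file.path(out_dir, "stability.csv"))
      outputs <- add_output(outputs, "stability.json", 1L)
      outputs <- add_output(outputs, "stability.csv",
                            length(stab$correlations))
    } else {
      note <- c(note, "too few pre-reward neurons for stability analysis")
    }

    beh <- behavior_summary(events,
                            response_window = pars$response_window %||% 2)
    write_csv_atomic(beh$psth, file.path(out_dir, "lick_psth.csv"))
    write_json_atomic(
      list(response_rate = beh$response_rate,
           mean_reaction_time_s = beh$reaction$mean_rt,
           sem_reaction_time_s = beh$reaction$sem_rt,
           n_responsive = beh$reaction$n),
      file.path(out_dir, "behavior.json"))
    outputs <- add_output(outputs, "lick_psth.csv", nrow(beh$psth))
    outputs <- add_output(outputs, "behavior.json", 1L)
  }

  manifest <- list(
    package = "deepcalseq",
    version = as.character(utils::packageVersion("deepcalseq")),
    workflow = config$workflow,
    rng_seed = seed,
    parameters = unclass(config),
    outputs = outputs,
    notes = note
  )
  write_json_atomic(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
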