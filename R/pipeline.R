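run_config_schema <- list(
  input = c("csv", "sidecar"),
  simulate = c("type", "seed", "snr_db", "n_segments", "n_silent",
               "n_baseline", "segment_length", "ramp_slope", "muscles",
               "voltage_ladder", "pulses_per_event", "thresholds",
               "frequency", "noise_sd", "amp_gain", "impulse_offset_ms",
               "sampling_rate"),
  outdir = NULL,
  channels = NULL,
  mode = NULL,
  ggmrf = c("sigma", "lam", "p", "q", "b", "radius", "max_iters", "tol",
            "enabled"),
  detector = c("method", "fraction", "quorum", "sigma_floor", "symmetric",
               "compute_onsets", "target_rate", "onset_window_ms",
               "onset_mult"),
  viz = c("png", "width", "height"),
  seed = NULL,
  verbose = NULL
)

#' Validate a pipeline run configuration
#'
#' Accepts a named list or a path to a JSON file. Unknown keys (top-level or
#' nested) are rejected so typos never silently fall back to defaults.
#' Exactly one of `input` (paths to a recording CSV + sidecar) or `simulate`
#' (spec of a synthetic session or benchmark) must be present; `outdir` is
#' required.
#'
#' @param config Named list or JSON file path.
#' @return The validated config (class `run_config`), with defaults filled.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or JSON path",
                             call. = FALSE)
  unknown <- setdiff(names(config), names(run_config_schema))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in names(config)) {
    allowed <- run_config_schema[[key]]
    if (!is.null(allowed) && is.list(config[[key]])) {
      bad <- setdiff(names(config[[key]]), allowed)
      if (length(bad) > 0L) {
        stop(sprintf("unknown key(s) under `%s`: %s", key,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stop("exactly one of `input` or `simulate` must be given", call. = FALSE)
  }
  if (is.null(config$outdir)) stop("`outdir` is required", call. = FALSE)
  config$mode <- config$mode %||% "intensity"
  if (!config$mode %in% c("intensity", "frequency")) {
    stop("`mode` must be 'intensity' or 'frequency'", call. = FALSE)
  }
  config$seed <- config$seed %||% 1L
  config$verbose <- isTRUE(config$verbose)
  structure(config, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

config_ggmrf <- function(config) {
  g <- config$ggmrf %||% list()
  g$enabled <- NULL
  do.call(ggmrf_params, g)
}

ggmrf_enabled <- function(config) {
  g <- config$ggmrf %||% list()
  g$enabled %||% TRUE
}

pipeline_recording <- function(config) {
  if (!is.null(config$input)) {
    rec <- read_recording(config$input$csv, config$input$sidecar)
    truth <- attr(rec, "truth")
    return(list(recording = rec, truth = truth, sim_spec = NULL))
  }
  sim_cfg <- config$simulate
  type <- sim_cfg$type %||% "session"
  args <- sim_cfg[setdiff(names(sim_cfg), "type")]
  args$seed <- args$seed %||% config$seed
  if (type == "session") {
    spec <- do.call(session_spec, args)
    sim <- simulate_mapping_session(spec)
  } else if (type == "benchmark") {
    spec <- do.call(benchmark_spec, args)
    sim <- simulate_benchmark_signal(spec)
  } else {
    stop("`simulate$type` must be 'session' or 'benchmark'", call. = FALSE)
  }
  list(recording = sim$recording, truth = sim$truth, sim_spec = spec)
}

#' Run the full analysis pipeline
#'
#' Executes segment -> denoise -> detect -> features -> visualize on every
#' requested channel and writes all artifacts under `outdir`: per-muscle
#' segment matrices (raw and smoothed), detection JSONs, feature CSVs, the
#' recruitment map (CSV + optional PNG), a config echo sufficient to
#' reproduce the run, and — when ground truth is available — a metrics JSON.
#' Intensity mode renders peak-to-peak maps with threshold masking;
#' frequency mode renders integrated-EMG maps.
#'
#' @param config A [run_config()] (or list/path coercible to one).
#' @return Invisibly, a named list of written paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  src <- pipeline_recording(config)
  rec <- src$recording
  channels <- config$channels %||% rec$channel_labels
  is_benchmark <- !is.null(src$sim_spec) &&
    inherits(src$sim_spec, "benchmark_spec")
  det_cfg <- config$detector %||% list()
  method <- det_cfg$method %||% "aglr"
  gp <- config_ggmrf(config)
  smooth <- ggmrf_enabled(config) && method == "aglr"
  paths <- list()
  features <- list()
  detections <- list()
  out <- function(...) file.path(config$outdir, paste0(...))

  for (ch in channels) {
    pipeline_log(config, "channel %s: segmenting", ch)
    seg <- segment_by_onsets(rec, ch)
    paths[[paste0("segments_", ch)]] <-
      write_segment_matrix(seg, out("segments_", ch, ".csv"),
                           out("segments_", ch, ".json"))
    work <- seg
    if (smooth) {
      pipeline_log(config, "channel %s: GGMRF denoising", ch)
      work <- ggmrf_denoise(seg, gp)
      paths[[paste0("smoothed_", ch)]] <-
        write_segment_matrix(work, out("smoothed_", ch, ".csv"),
                             out("smoothed_", ch, ".json"))
    }
    pipeline_log(config, "channel %s: %s detection", ch, method)
    baseline_rows <- if (is_benchmark) seq_len(src$sim_spec$n_baseline)
    det <- if (method == "tkeo") {
      detect_tkeo(work,
                  baseline_rows = baseline_rows,
                  quorum = det_cfg$quorum %||% 0.5)
    } else {
      detect_aglr(work, baseline_rows = baseline_rows,
                  fraction = det_cfg$fraction %||% 1 / 8,
                  sigma_floor = det_cfg$sigma_floor %||% 1e-6,
                  quorum = det_cfg$quorum %||% 0.5,
                  symmetric = isTRUE(det_cfg$symmetric),
                  compute_onsets = det_cfg$compute_onsets %||% TRUE,
                  target_rate = det_cfg$target_rate %||% 10000,
                  onset_window_ms = det_cfg$onset_window_ms %||% 2,
                  onset_mult = det_cfg$onset_mult %||% 3)
    }
    detections[[ch]] <- det
    paths[[paste0("detection_", ch)]] <-
      write_detection(det, out("detection_", ch, ".json"))
    ft <- build_feature_table(seg, det)
    features[[ch]] <- ft
    readr::write_csv(ft, out("features_", ch, ".csv"))
    paths[[paste0("features_", ch)]] <- out("features_", ch, ".csv")
  }

  if (!is_benchmark && length(channels) > 1L) {
    map <- if (config$mode == "intensity") {
      intensity_map(features, detections)
    } else {
      frequency_map(features)
    }
    viz_cfg <- config$viz %||% list()
    png_path <- if (viz_cfg$png %||% TRUE) out("map.png")
    paths$map <- write_map(map, out("map.csv"), png_path,
                           width = viz_cfg$width %||% 8,
                           height = viz_cfg$height %||% 5)
  }

  if (!is.null(src$truth)) {
    truths <- if (inherits(src$truth, "ground_truth")) {
      setNames(list(src$truth), rec$channel_labels[1L])
    } else {
      src$truth
    }
    scored <- lapply(channels, function(ch) {
      tr <- truths[[ch]]
      if (is.null(tr)) return(NULL)
      flags <- as.logical(tr$active)
      pred <- detections[[ch]]$segment_active
      n <- min(length(flags), length(pred)) # trailing pulse may be dropped
      m <- metrics(confusion(pred[seq_len(n)], flags[seq_len(n)]))
      list(muscle = ch, metrics = as.list(m))
    })
    scored <- Filter(Negate(is.null), scored)
    if (length(scored) > 0L) {
      write_json_file(scored, out("metrics.json"))
      paths$metrics <- out("metrics.json")
    }
  }

  echo <- unclass(config)
  echo$package_version <- as.character(utils::packageVersion("scesmap"))
  write_json_file(echo, out("config_echo.json"))
  paths$config_echo <- out("config_echo.json")
  pipeline_log(config, "pipeline finished in %.2f s",
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(paths)
}
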