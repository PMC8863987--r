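#' Pipeline run configuration
#'
#' Collects every knob of the standard workflow (burst search -> selection
#' -> BVA -> model scan -> ICL selection -> Viterbi dwell analysis) in one
#' validated object that round-trips losslessly to YAML or JSON.
#'
#' @param input Path to a photon-HDF5 or plain-text photon table, or `NULL`
#'   when `simulate` is given.
#' @param simulate Optional [sim_scenario()] to generate the input instead
#'   of reading a file.
#' @param mode `"nsALEX"` or `"usALEX"` (used when the input needs stream
#'   assignment).
#' @param scheme Optional [alternation_scheme()] for stream assignment /
#'   the acceptor shift.
#' @param detector_map Detector-to-emission-channel map for
#'   [assign_streams()] (`NULL` when the input already carries streams).
#' @param search `"all"` (single sliding-window search over all photons) or
#'   `"dcbs"` (dual-channel).
#' @param m,F,min_photons Burst search and selection parameters.
#' @param bg_slice_seconds Background slice length.
#' @param bva_window BVA window size in photons.
#' @param streams `c(0, 1, 2)` for multi-parameter analysis, `c(0, 1)` for
#'   single-parameter (donor-excitation only).
#' @param q_max Largest state count in the scan.
#' @param max_iter,tol Optimizer settings.
#' @param seed Seed for initialization (and simulation, if any).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       mode = c("nsALEX", "usALEX"), scheme = NULL,
                       detector_map = NULL,
                       search = c("all", "dcbs"), m = 10L, F = 6,
                       min_photons = 30L, bg_slice_seconds = 30,
                       bva_window = 5L, streams = c(0L, 1L, 2L),
                       q_max = 6L, max_iter = 1000L, tol = 1e-3,
                       seed = 1L) {
  mode <- match.arg(mode)
  search <- match.arg(search)
  if (is.null(input) && is.null(simulate))
    stop("either an input path or a simulation scenario is required")
  stopifnot(m >= 2, F > 0, min_photons >= 1, q_max >= 1)
  structure(list(input = input, simulate = simulate, mode = mode,
                 scheme = scheme, detector_map = detector_map,
                 search = search, m = as.integer(m), F = F,
                 min_photons = as.integer(min_photons),
                 bg_slice_seconds = bg_slice_seconds,
                 bva_window = as.integer(bva_window),
                 streams = as.integer(streams), q_max = as.integer(q_max),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration
#'
#' YAML (default) or JSON, by file extension. Scenario and scheme objects
#' are stored as plain lists and reconstructed on read.
#'
#' @param config A `run_config`.
#' @param path File ending in `.yaml`, `.yml` or `.json`.
#' @return `read_run_config` returns the `run_config`; the writer returns
#'   `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$simulate)) {
    x$simulate <- unclass(x$simulate)
    x$simulate$rate_matrix <- as.data.frame(x$simulate$rate_matrix)
    if (!is.null(x$simulate$scheme))
      x$simulate$scheme <- unclass(x$simulate$scheme)
  }
  if (!is.null(x$scheme)) x$scheme <- unclass(x$scheme)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  rebuild_scheme <- function(s) if (is.null(s)) NULL else
    alternation_scheme(s$mode, s$alternation_period,
                       unlist(s$donor_window), unlist(s$acceptor_window),
                       unlist(s$donor_nanotime_range),
                       unlist(s$acceptor_nanotime_range))
  sim <- NULL
  if (!is.null(x$simulate)) {
    s <- x$simulate
    sim <- sim_scenario(as.data.frame(s$states),
                        unname(as.matrix(as.data.frame(s$rate_matrix))),
                        n_bursts = s$n_bursts,
                        burst_duration_mean = s$burst_duration_mean,
                        burst_duration_dist = s$burst_duration_dist,
                        inter_burst_mean = s$inter_burst_mean,
                        background = unlist(s$background),
                        clock_period = s$clock_period, mode = s$mode,
                        scheme = rebuild_scheme(s$scheme), seed = s$seed)
  }
  run_config(input = x$input, simulate = sim, mode = x$mode,
             scheme = rebuild_scheme(x$scheme),
             detector_map = if (is.null(x$detector_map)) NULL
                            else unlist(x$detector_map),
             search = x$search, m = x$m, F = x$F,
             min_photons = x$min_photons,
             bg_slice_seconds = x$bg_slice_seconds,
             bva_window = x$bva_window, streams = unlist(x$streams),
             q_max = x$q_max, max_iter = x$max_iter, tol = x$tol,
             seed = x$seed)
}

#' Run the full analysis pipeline
#'
#' Executes the standard workflow on one dataset and writes every artifact
#' into `out_dir`: `bursts.csv`, `bva.csv`, `scan.csv` + `selected.json`,
#' `model.csv` (selected state model), `dwells.csv`,
#' `classification.csv`, per-state `dwell_stats.csv`, a `manifest.json`
#' (package version, seed, parameters, per-stage counts and timings) and a
#' plain-text `log.txt`. Identical config and seed give identical outputs.
#' If a stage fails, the artifacts produced so far are kept and the
#' manifest records the failed stage.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results (`series`,
#'   `bursts`, `bva`, `scan`, `fit`, `dwells`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  manifest <- list(package = "mph2mm",
                   version = as.character(packageVersion("mph2mm")),
                   seed = config$seed, stages = list(),
                   parameters = list(m = config$m, F = config$F,
                                     min_photons = config$min_photons,
                                     search = config$search,
                                     streams = config$streams,
                                     q_max = config$q_max,
                                     tol = config$tol))
  res <- list()
  t_stage <- function(nm, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) e)
    manifest$stages[[nm]] <<- list(
      seconds = round(proc.time()[3] - t0, 3),
      status = if (inherits(out, "error")) paste("failed:",
                                                 conditionMessage(out))
               else "ok")
    if (inherits(out, "error")) {
      logf("stage %s FAILED: %s", nm, conditionMessage(out))
      stop_pipeline <<- TRUE
      return(NULL)
    }
    out
  }
  stop_pipeline <- FALSE
  write_manifest <- function() jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE, null = "null", force = TRUE)
  on.exit(write_manifest())

  # --- input ---
  series <- t_stage("input", {
    if (!is.null(config$simulate)) {
      ds <- make_dataset(config$simulate, seed = config$seed)
      logf("simulated %d photons in %d true bursts",
           length(ds$series$timestamps), nrow(ds$bursts))
      ds$series
    } else {
      s <- if (grepl("\\.(h5|hdf5)$", config$input)) {
        rd <- read_photon_hdf5(config$input)
        if (is.null(config$scheme) && !is.null(rd$scheme))
          config$scheme <- rd$scheme
        rd$series
      } else read_photon_table(config$input)
      manifest$input <- list(path = config$input,
                             md5 = unname(tools::md5sum(config$input)))
      logf("read %d photons from %s", length(s$timestamps), config$input)
      s
    }
  })
  if (stop_pipeline) return(invisible(res))
  if (!isTRUE(attr(series, "streams_assigned"))) {
    series <- t_stage("assign_streams", {
      s <- assign_streams(series, config$scheme, config$detector_map)
      logf("assigned streams; %d photons dropped",
           attr(s, "dropped_photons"))
      s
    })
    if (stop_pipeline) return(invisible(res))
  }
  if (config$mode == "usALEX" && !is.null(config$scheme)) {
    series <- t_stage("shift", shift_acceptor_photons(series,
                                                      config$scheme))
  } else if (config$mode == "usALEX" && !is.null(config$simulate)) {
    series <- t_stage("shift", shift_acceptor_photons(
      series, config$simulate$scheme))
  }
  if (stop_pipeline) return(invisible(res))
  res$series <- series
  manifest$counts <- list(photons = length(series$timestamps))

  # --- burst search & selection ---
  bursts <- t_stage("burst_search", {
    if (config$search == "dcbs") {
      b <- dcbs_search(series, m = config$m, F = config$F,
                       slice_seconds = config$bg_slice_seconds)
    } else {
      bg <- estimate_background(series, config$bg_slice_seconds)
      b <- sliding_burst_search(series, bg, m = config$m, F = config$F)
    }
    logf("burst search (%s): %d bursts", config$search, nrow(b))
    b
  })
  if (stop_pipeline) return(invisible(res))
  bursts <- t_stage("burst_selection", {
    b <- select_bursts(bursts, config$min_photons)
    logf("selection (>= %d photons): %d bursts", config$min_photons,
         nrow(b))
    b
  })
  if (stop_pipeline) return(invisible(res))
  res$bursts <- bursts
  write_bursts_csv(bursts, file.path(out_dir, "bursts.csv"))
  manifest$counts$bursts <- nrow(bursts)

  # --- BVA ---
  res$bva <- t_stage("bva", {
    v <- bva(series, bursts, config$bva_window)
    write.csv(as.data.frame(v), file.path(out_dir, "bva.csv"),
              row.names = FALSE)
    v
  })

  # --- model scan ---
  scan_out <- t_stage("scan", {
    data <- as_obs_set(series, bursts, streams = config$streams)
    logf("optimizing state models, r = %d, %d photons", data$r, data$n)
    sc <- h2mm_scan(data, q_max = config$q_max, max_iter = config$max_iter,
                    tol = config$tol, seed = config$seed)
    logf("selected q = %d (%s)", sc$selected_q, sc$rationale)
    list(data = data, scan = sc)
  })
  if (stop_pipeline) return(invisible(res))
  res$data <- scan_out$data
  scan <- scan_out$scan
  res$scan <- scan
  write_scan_csv(scan, file.path(out_dir, "scan.csv"),
                 file.path(out_dir, "selected.json"))
  manifest$selected_q <- scan$selected_q
  manifest$r <- scan$r
  manifest$K_selected <- n_free_params(scan$selected_q, scan$r)
  fit <- scan_fit(scan)
  res$fit <- fit
  write_state_model_csv(fit, file.path(out_dir, "model.csv"))
  manifest$counts$em_iterations <- fit$niter

  # --- Viterbi analysis ---
  res$dwells <- t_stage("viterbi", {
    vit <- viterbi(fit$model, res$data)
    dwells <- segment_dwells(vit$paths, res$data)
    write_dwells_csv(dwells, file.path(out_dir, "dwells.csv"))
    cls <- classify_bursts(vit$paths)
    write.csv(cls, file.path(out_dir, "classification.csv"),
              row.names = FALSE)
    stats <- weighted_dwell_stats(dwells)
    write.csv(stats, file.path(out_dir, "dwell_stats.csv"),
              row.names = FALSE)
    jsonlite::write_json(stats, file.path(out_dir, "dwell_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf("viterbi: %d dwells across %d bursts", nrow(dwells),
         length(vit$paths))
    dwells
  })
  res$manifest <- manifest
  invisible(res)
}
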