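# File formats and configuration. Traces are columnar CSV (time_s, ch1_v,
# ch2_v, artifact_v) with a JSON sidecar carrying sampling rate, geometry
# and protocol; events and response tables are plain CSV.

.protocol_to_list <- function(protocol) {
  lapply(protocol, function(ev) {
    out <- list(modality = ev$modality, onset = ev$onset)
    if (!is.null(ev$leus))
      out$leus <- ev$leus[c("f", "n_cycles", "prf", "n_pulses", "p_a")]
    out
  })
}

.protocol_from_list <- function(lst) {
  lapply(lst, function(e) {
    leus <- if (!is.null(e$leus))
      leus_sequence(e$leus$f, e$leus$n_cycles, e$leus$prf, e$leus$n_pulses,
                    e$leus$p_a)
    stimulus_event(e$modality, e$onset, leus)
  })
}

#' Write / read a recording trace
#'
#' `write_trace` stores the samples as CSV (`time_s`, `ch1_v`, `ch2_v`,
#' `artifact_v`) at full precision plus a JSON sidecar (`<path>.json`) with
#' the sampling rate, electrode geometry and protocol. `read_trace`
#' round-trips it, validating the schema, time monotonicity and the
#' consistency of the declared sampling rate with the time column.
#'
#' @param trace A [recording_trace()].
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [recording_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "recording_trace"))
  n <- length(trace$channels$ch1)
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1L) / trace$sampling_rate,
    ch1_v = trace$channels$ch1, ch2_v = trace$channels$ch2,
    artifact_v = trace$channels$artifact)
  data.table::fwrite(dt, path)
  side <- list(sampling_rate = trace$sampling_rate)
  if (!is.null(trace$geometry))
    side$geometry <- list(
      stim_to_first_anode = trace$geometry$stim_to_first_anode,
      electrode_spacing = trace$geometry$anode_cathode_separation)
  if (!is.null(trace$protocol))
    side$protocol <- .protocol_to_list(trace$protocol)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  dt <- data.table::fread(path)
  need <- c("time_s", "ch1_v", "ch2_v", "artifact_v")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("trace file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(dt) < 2 || is.unsorted(dt$time_s, strictly = TRUE))
    stop("trace time column must be strictly increasing (", path, ")")
  fs_obs <- 1 / stats::median(diff(dt$time_s))
  geometry <- NULL; protocol <- NULL; fs <- fs_obs
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
    fs <- side$sampling_rate
    if (abs(fs - fs_obs) / fs > 0.01)
      stop("sampling-rate mismatch: sidecar says ", fs,
           " Hz but time column implies ", round(fs_obs), " Hz")
    if (!is.null(side$geometry))
      geometry <- electrode_geometry(side$geometry$stim_to_first_anode,
                                     side$geometry$electrode_spacing)
    if (!is.null(side$protocol))
      protocol <- .protocol_from_list(side$protocol)
  }
  recording_trace(fs, dt$ch1_v, dt$ch2_v, dt$artifact_v, geometry, protocol)
}

#' Write / read a detected-event table
#'
#' CSV schema: `channel`, `t_pos_s`, `t_neg_s`, `amplitude_v`,
#' `lobe_separation_s`, `quality`, `saturated`. Reading enforces the
#' biphasic invariant `t_neg_s > t_pos_s` with a line-numbered error.
#'
#' @param events Event table from [detect_aps()].
#' @param path CSV file path.
#' @return `write_events` returns `path` invisibly; `read_events` the
#'   validated data.frame.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(data.table::as.data.table(events), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  need <- c("channel", "t_pos_s", "t_neg_s", "amplitude_v")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("events file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(dt$t_neg_s <= dt$t_pos_s)
  if (length(bad))
    stop("events file ", path, ": negative lobe precedes positive lobe at ",
         "line(s) ", paste(bad + 1L, collapse = ", "))
  dt
}

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter with its documented default:
#' analysis band 120-1200 Hz, robust detection threshold k = 4, 2 ms
#' post-onset blanking for EStim/MStim and none for UStim trigger ticks,
#' lobe pairing window 0.3-3 ms, matching velocity window 3-30 m/s,
#' 12 m/s MGF/LGF boundary, 200 ms response window, 1 cm electrode spacing
#' at 8.4 cm from the stimulation site, 40 kHz sampling, noise SD 5% of the
#' MGF peak amplitude, and the default comparative MStim-vs-UStim trial.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(noise_sd = 5e-5, sampling_rate = 4e4,
                    lobe_width = 1.5e-3),
    filter = list(low_hz = 120, high_hz = 1200, order = 4),
    detect = list(threshold_k = 4,
                  blanking_ms = list(EStim = 2, MStim = 2, UStim = 0),
                  lobe_window_ms = c(0.3, 3), min_neg_ratio = 0.4,
                  dead_time_ms = 3, rel_floor = 0.1),
    match = list(velocity_window = c(3, 30)),
    classify = list(velocity_boundary = 12, amplitude_boundary = NULL),
    response = list(window_s = 0.2),
    geometry = list(stim_to_first_anode = 0.084, electrode_spacing = 0.01),
    trial = list(modalities = c("MStim", "UStim"), n_per_modality = 40,
                 start_s = 0.2, interval_s = 0.25,
                 leus = list(f = 1.1e6, n_cycles = 175, prf = 125,
                             n_pulses = 20, p_a = 6.6e6))
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    here <- paste0(path, if (nzchar(path)) ".", k)
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", here)
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])))
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], here)
    else
      defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read a pipeline configuration
#'
#' Reads a JSON document and merges it over [default_config()]. Unknown
#' keys are rejected with the offending path.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return Full configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  .merge_config(cfg, user)
}

#' Provenance hash of a configuration
#'
#' MD5 of the canonical JSON rendering; changes iff the configuration
#' changes.
#'
#' @param config Configuration list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(f))
}
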