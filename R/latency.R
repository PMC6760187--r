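# Cross-channel AP matching, fiber classification and the latency
# decomposition: arrival delay = TOP + TOG.

#' Match detected APs across the two recording sites
#'
#' Pairs events detected on channel 1 (closer to the stimulation site) with
#' events on channel 2, greedily in time order and one-to-one: a pair is
#' valid iff the implied conduction velocity, anode separation divided by
#' the inter-site positive-peak delay, lies in `velocity_window`. Events
#' that cannot be paired (including degenerate zero-delay coincidences,
#' whose implied velocity is infinite) are left unmatched and counted.
#'
#' @param events_ch1,events_ch2 Event tables from [detect_aps()] (rows for
#'   one channel each), sorted by time.
#' @param geometry An [electrode_geometry()]; its `anode_separation` sets
#'   the velocity scale. Missing geometry is an error.
#' @param velocity_window Admissible velocity range, m/s.
#' @return data.frame of propagated APs with columns `t_pos1_s`, `t_neg1_s`,
#'   `t_pos2_s`, `amplitude_v` (channel-1 amplitude), `velocity_mps`,
#'   `quality`; attributes `n_unmatched_ch1`, `n_unmatched_ch2`.
#' @export
match_across_channels <- function(events_ch1, events_ch2, geometry,
                                  velocity_window = c(3, 30)) {
  if (missing(geometry) || !inherits(geometry, "electrode_geometry"))
    stop("electrode geometry is required to convert delays to velocities")
  stopifnot(length(velocity_window) == 2,
            velocity_window[1] > 0, velocity_window[1] < velocity_window[2])
  sep <- geometry$anode_separation
  empty <- data.frame(t_pos1_s = numeric(), t_neg1_s = numeric(),
                      t_pos2_s = numeric(), amplitude_v = numeric(),
                      velocity_mps = numeric(), quality = numeric(),
                      stringsAsFactors = FALSE)
  n1 <- nrow(events_ch1); n2 <- nrow(events_ch2)
  if (!n1 || !n2) {
    attr(empty, "n_unmatched_ch1") <- if (is.null(n1)) 0L else n1
    attr(empty, "n_unmatched_ch2") <- if (is.null(n2)) 0L else n2
    return(empty)
  }
  t1 <- events_ch1$t_pos_s; t2 <- events_ch2$t_pos_s
  dt_min <- sep / velocity_window[2]   # fastest admissible
  dt_max <- sep / velocity_window[1]   # slowest admissible
  pairs <- list(); j <- 1L; used1 <- logical(n1)
  for (i in seq_len(n1)) {
    # ch2 events too early for this (and any later) ch1 event can never match
    while (j <= n2 && t2[j] < t1[i] + dt_min) j <- j + 1L
    if (j > n2) break
    if (t2[j] <= t1[i] + dt_max) {
      dt <- t2[j] - t1[i]
      pairs[[length(pairs) + 1L]] <- data.frame(
        t_pos1_s = t1[i], t_neg1_s = events_ch1$t_neg_s[i],
        t_pos2_s = t2[j], amplitude_v = events_ch1$amplitude_v[i],
        velocity_mps = sep / dt,
        quality = min(events_ch1$quality[i], events_ch2$quality[j]),
        stringsAsFactors = FALSE)
      used1[i] <- TRUE
      j <- j + 1L
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else empty
  attr(out, "n_unmatched_ch1") <- sum(!used1)
  attr(out, "n_unmatched_ch2") <- n2 - sum(used1)
  out
}

#' Classify a propagated AP as MGF or LGF
#'
#' The two giant-fiber classes are distinguishable by conduction velocity
#' and amplitude. The primary rule is the velocity boundary (default
#' 12 m/s, midway between the two reported velocity ranges): at or above it
#' MGF, below it LGF; an AP exactly on the boundary goes to the faster
#' class. When an amplitude boundary is supplied the amplitude vote must
#' agree, otherwise the AP is labelled `UNKNOWN`.
#'
#' @param velocity Conduction velocity, m/s (vectorized).
#' @param amplitude Optional event amplitude, volts.
#' @param velocity_boundary MGF/LGF velocity boundary, m/s.
#' @param amplitude_boundary Optional MGF/LGF amplitude boundary, volts;
#'   `NULL` disables the amplitude criterion.
#' @return Character vector: `"MGF"`, `"LGF"` or `"UNKNOWN"`.
#' @export
classify_fiber <- function(velocity, amplitude = NULL,
                           velocity_boundary = 12,
                           amplitude_boundary = NULL) {
  stopifnot(velocity_boundary > 0)
  cls <- ifelse(velocity >= velocity_boundary, "MGF", "LGF")
  if (!is.null(amplitude_boundary) && !is.null(amplitude)) {
    amp_cls <- ifelse(amplitude >= amplitude_boundary, "MGF", "LGF")
    cls[cls != amp_cls] <- "UNKNOWN"
  }
  cls
}

#' Time of propagation (TOP)
#'
#' Time for an AP to travel the axonal distance between the point of
#' stimulation and the recording anode, at the trial-mean conduction
#' velocity of its fiber class.
#'
#' @param axonal_distance Distance from stimulation point to the recording
#'   anode, metres (> 0).
#' @param mean_velocity Mean conduction velocity, m/s (> 0).
#' @return TOP in seconds.
#' @export
compute_top <- function(axonal_distance, mean_velocity) {
  if (any(!is.finite(axonal_distance)) || any(axonal_distance <= 0) ||
      any(!is.finite(mean_velocity)) || any(mean_velocity <= 0))
    stop("axonal_distance and mean_velocity must be positive and finite")
  axonal_distance / mean_velocity
}

#' Time of generation (TOG)
#'
#' TOG = arrival delay - TOP: the latency attributable to transduction,
#' afferent conduction and synaptic integration upstream of the giant axon.
#' Negative values are physiologically implausible; they are returned as-is
#' (flagged downstream, never clipped).
#'
#' @param arrival_delay Delay from stimulus onset to AP peak at the
#'   recording anode, s.
#' @param top Time of propagation, s (>= 0).
#' @return TOG in seconds.
#' @export
compute_tog <- function(arrival_delay, top) {
  if (isTRUE(any(top < 0, na.rm = TRUE))) stop("top must be non-negative")
  arrival_delay - top
}

#' Group propagated APs by stimulus
#'
#' Assigns each AP to the most recent onset whose arrival delay (channel-1
#' positive-peak time minus onset) is at most `response_window`, and rolls
#' up a per-stimulus response record. APs preceding the first onset or
#' falling outside every window are left unassigned and reported.
#'
#' @param onsets Onset table from [detect_stimulus_onsets()] (columns
#'   `stimulus_id`, `onset_s`, `modality`), sorted by time.
#' @param paps Propagated-AP table from [match_across_channels()].
#' @param response_window Maximum admissible arrival delay, s.
#' @return List with `responses` (one row per stimulus: `stimulus_id`,
#'   `modality`, `onset_s`, `responded`, `ap_count`) and `aps` (the input
#'   table plus `stimulus_id`, `dt_s`); attribute `n_unassigned` on `aps`.
#' @export
assemble_responses <- function(onsets, paps, response_window = 0.2) {
  stopifnot(is.data.frame(onsets), response_window > 0)
  if (nrow(onsets) && is.unsorted(onsets$onset_s, strictly = TRUE))
    stop("onsets must be strictly increasing")
  aps <- paps
  aps$stimulus_id <- rep(NA_integer_, nrow(aps))
  aps$dt_s <- rep(NA_real_, nrow(aps))
  if (nrow(aps) && nrow(onsets)) {
    idx <- findInterval(aps$t_pos1_s, onsets$onset_s)
    ok <- idx >= 1L
    dt <- ifelse(ok, aps$t_pos1_s - onsets$onset_s[pmax(idx, 1L)], NA_real_)
    ok <- ok & dt <= response_window
    aps$stimulus_id[ok] <- onsets$stimulus_id[idx[ok]]
    aps$dt_s[ok] <- dt[ok]
  }
  counts <- if (nrow(aps))
    table(factor(aps$stimulus_id, levels = onsets$stimulus_id))
  else
    table(factor(integer(), levels = onsets$stimulus_id))
  responses <- data.frame(stimulus_id = onsets$stimulus_id,
                          modality = onsets$modality,
                          onset_s = onsets$onset_s,
                          responded = as.integer(counts) >= 1L,
                          ap_count = as.integer(counts),
                          stringsAsFactors = FALSE)
  attr(aps, "n_unassigned") <- sum(is.na(aps$stimulus_id))
  list(responses = responses, aps = aps)
}

#' Success rate of a set of administered stimuli
#'
#' Number of stimuli that evoked at least one AP divided by the number
#' administered. Invariant to record order and duplication of every record.
#'
#' @param records Response table from [assemble_responses()] (or a logical
#'   vector of responded flags).
#' @return Fraction in \[0, 1\].
#' @export
success_rate <- function(records) {
  responded <- if (is.data.frame(records)) records$responded else records
  if (!length(responded)) stop("success_rate of zero administered stimuli")
  mean(as.logical(responded))
}

#' Full single-trace latency analysis
#'
#' Runs the per-trace analysis chain: band-pass filter, stimulus-onset
#' detection, per-channel biphasic AP detection (with artifact blanking),
#' cross-channel matching, fiber classification, per-class trial-mean
#' velocity, and the latency decomposition dt = TOP + TOG per AP. Negative
#' TOGs are flagged implausible (`plausible = FALSE`) and meant to be
#' excluded from summaries, never clipped.
#'
#' @param trace A raw [recording_trace()] (filtering is applied here).
#' @param threshold_k Detection threshold in robust-SD units.
#' @param low,high Analysis band, Hz.
#' @param blanking_s Post-onset blanking, scalar or named by modality.
#' @param velocity_window Admissible velocity range for matching, m/s.
#' @param velocity_boundary MGF/LGF classification boundary, m/s.
#' @param amplitude_boundary Optional amplitude boundary, volts.
#' @param response_window Maximum arrival delay, s.
#' @param axonal_distance Stimulation-to-first-anode distance, m; default
#'   taken from the trace geometry.
#' @return List with `onsets`, `events`, `aps` (per-AP table with
#'   `stimulus_id`, `fiber`, `velocity_mps`, `dt_s`, `top_s`, `tog_s`,
#'   `plausible`), `responses`, and `class_velocity` (named per-class mean).
#' @export
analyze_trace <- function(trace, threshold_k = 4, low = 120, high = 1200,
                          blanking_s = c(EStim = 2e-3, MStim = 2e-3,
                                         UStim = 0),
                          velocity_window = c(3, 30),
                          velocity_boundary = 12,
                          amplitude_boundary = NULL,
                          response_window = 0.2,
                          axonal_distance = NULL) {
  stopifnot(inherits(trace, "recording_trace"))
  if (is.null(axonal_distance)) {
    if (is.null(trace$geometry)) stop("axonal_distance required (no geometry)")
    axonal_distance <- trace$geometry$stim_to_first_anode
  }
  filt <- bandpass_filter(trace, low, high)
  onsets <- detect_stimulus_onsets(trace)
  events <- detect_aps(filt, threshold_k = threshold_k, onsets = onsets,
                       blanking_s = blanking_s)
  paps <- match_across_channels(events[events$channel == "ch1", , drop = FALSE],
                                events[events$channel == "ch2", , drop = FALSE],
                                trace$geometry, velocity_window)
  asm <- assemble_responses(onsets, paps, response_window)
  aps <- asm$aps
  aps$fiber <- if (nrow(aps))
    classify_fiber(aps$velocity_mps, aps$amplitude_v,
                   velocity_boundary, amplitude_boundary)
  else character()
  # trial-mean velocity per fiber class -> per-class TOP
  cls_v <- tapply(aps$velocity_mps[aps$fiber != "UNKNOWN"],
                  aps$fiber[aps$fiber != "UNKNOWN"], mean)
  aps$top_s <- NA_real_
  known <- aps$fiber %in% names(cls_v)
  if (any(known))
    aps$top_s[known] <- compute_top(axonal_distance,
                                    as.numeric(cls_v[aps$fiber[known]]))
  aps$tog_s <- compute_tog(aps$dt_s, ifelse(is.na(aps$top_s), 0, aps$top_s))
  aps$tog_s[is.na(aps$top_s)] <- NA_real_
  aps$plausible <- !is.na(aps$tog_s) & aps$tog_s >= 0
  list(onsets = onsets, events = events, aps = aps,
       responses = asm$responses,
       class_velocity = cls_v)
}
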