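# Band-pass filtering and biphasic AP detection.

#' Zero-phase band-pass filter a signal
#'
#' Applies the squared magnitude response of a 4th-order analog Butterworth
#' band-pass filter in the frequency domain. This is the transfer function a
#' forward-backward (filtfilt) application of the same filter realizes:
#' strictly zero phase, so event peak times are not shifted, with DC and
#' slow drift removed.
#'
#' @param x Numeric signal, volts.
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz (0 < low < high < fs/2).
#' @param order Butterworth order of the one-way prototype.
#' @return Filtered signal, same length as `x`.
#' @export
filter_signal <- function(x, fs, low = 120, high = 1200, order = 4) {
  stopifnot(low > 0, low < high, high < fs / 2)
  n <- length(x)
  if (n < ceiling(3 * fs / low))
    stop("trace shorter than filter warm-up length (need >= ",
         ceiling(3 * fs / low), " samples at ", fs, " Hz)")
  mu <- mean(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  w <- 2 * pi * abs(f)
  wl <- 2 * pi * low; wh <- 2 * pi * high
  bw <- wh - wl; w0sq <- wl * wh
  # analog band-pass Butterworth magnitude; |H|^2 applied once = filtfilt
  u <- ifelse(w > 0, (w^2 - w0sq) / (bw * w), Inf)
  gain <- 1 / (1 + u^(2 * order))
  Re(stats::fft(stats::fft(x - mu) * gain, inverse = TRUE)) / n
}

#' Band-pass filter a recording in the analysis band
#'
#' Filters both bipolar channels of a [recording_trace()] (default band
#' 120-1200 Hz, the acquisition band that keeps the baseline steady while
#' preserving the ~1 ms biphasic AP waveforms). The artifact channel is left
#' untouched: it is a timing channel whose step-like MStim transient must
#' keep its peak.
#'
#' @param trace A [recording_trace()].
#' @param low,high Band edges, Hz.
#' @param order Butterworth order.
#' @return A filtered copy of `trace`.
#' @export
bandpass_filter <- function(trace, low = 120, high = 1200, order = 4) {
  stopifnot(inherits(trace, "recording_trace"))
  if (trace$sampling_rate <= 2 * high)
    stop("sampling rate must exceed twice the high cutoff")
  out <- trace
  out$channels$ch1 <- filter_signal(trace$channels$ch1, trace$sampling_rate,
                                    low, high, order)
  out$channels$ch2 <- filter_signal(trace$channels$ch2, trace$sampling_rate,
                                    low, high, order)
  out
}

# Parabolic (three-point) refinement of a peak position; returns offset in
# samples within (-0.5, 0.5) and the interpolated extremum value.
.refine_peak <- function(x, i) {
  if (i <= 1L || i >= length(x)) return(c(offset = 0, value = x[i]))
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (denom == 0) return(c(offset = 0, value = x[i]))
  d <- 0.5 * (x[i - 1L] - x[i + 1L]) / denom
  d <- max(min(d, 0.5), -0.5)
  c(offset = d, value = x[i] - 0.25 * (x[i - 1L] - x[i + 1L]) * d)
}

# Local maxima above a threshold: one candidate (the run maximum) per
# contiguous suprathreshold run.
.runs_argmax <- function(x, thr) {
  above <- x > thr
  if (!any(above)) return(integer())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  vapply(keep, function(k) {
    i <- starts[k]:ends[k]
    i[which.max(x[i])]
  }, integer(1))
}

#' Detect stimulus onsets from the artifact channel
#'
#' One onset per artifact event: the positive peak of the artifact is the
#' per-modality time reference (EStim electromagnetic transient, MStim
#' contact artifact, UStim trigger tick). Peaks closer than `dead_time` are
#' merged (largest kept). If the trace carries a protocol, each onset is
#' labelled with the modality of the nearest declared stimulus and a warning
#' is issued when the detected count does not match the declared count.
#'
#' @param trace A [recording_trace()] (raw; the artifact channel is used).
#' @param threshold_frac Detection threshold as a fraction of the artifact
#'   channel maximum.
#' @param dead_time Minimum separation between distinct onsets, s.
#' @return data.frame with columns `stimulus_id`, `onset_s`, `modality`
#'   (NA when no protocol is attached), onsets strictly increasing.
#' @export
detect_stimulus_onsets <- function(trace, threshold_frac = 0.3,
                                   dead_time = 5e-3) {
  stopifnot(inherits(trace, "recording_trace"))
  x <- trace$channels$artifact
  fs <- trace$sampling_rate
  empty <- data.frame(stimulus_id = integer(), onset_s = numeric(),
                      modality = character(), stringsAsFactors = FALSE)
  mx <- max(x)
  n_declared <- length(trace$protocol)
  if (mx <= 0) {
    if (n_declared > 0)
      warning("0 onsets detected but protocol declares ", n_declared,
              " stimuli")
    return(empty)
  }
  cand <- .runs_argmax(x, threshold_frac * mx)
  # dead-time suppression, larger peak wins
  cand <- cand[order(x[cand], decreasing = TRUE)]
  acc <- integer()
  for (i in cand)
    if (!length(acc) || all(abs(i - acc) > dead_time * fs)) acc <- c(acc, i)
  acc <- sort(acc)
  out <- data.frame(stimulus_id = seq_along(acc), onset_s = (acc - 1L) / fs,
                    modality = NA_character_, stringsAsFactors = FALSE)
  if (n_declared > 0) {
    declared <- vapply(trace$protocol, `[[`, numeric(1), "onset")
    mods <- vapply(trace$protocol, `[[`, character(1), "modality")
    nearest <- vapply(out$onset_s, function(t) which.min(abs(declared - t)),
                      integer(1))
    out$modality <- mods[nearest]
    if (nrow(out) != n_declared)
      warning(nrow(out), " onsets detected but protocol declares ",
              n_declared, " stimuli")
  }
  out
}

#' Detect biphasic AP events on the bipolar channels
#'
#' Works on a band-passed trace. A candidate event is a positive excursion
#' above `threshold_k` times the robust baseline scale (1.4826 x MAD of the
#' filtered channel) followed, within the physiological lobe window, by a
#' negative excursion of comparable magnitude (the anode lobe precedes the
#' cathode lobe). Overlapping candidates within `dead_time` are resolved by
#' keeping the larger amplitude. Events whose positive peak falls inside a
#' blanking window after a stimulus onset are suppressed. Peak times are
#' refined to sub-sample precision by parabolic interpolation.
#'
#' @param trace A band-passed [recording_trace()].
#' @param threshold_k Threshold in robust-SD units (default 4).
#' @param lobe_window Allowed positive-to-negative lobe separation, s
#'   (default 0.3-3 ms: 1 cm anode-cathode span at 3-33 m/s).
#' @param onsets Optional onset table from [detect_stimulus_onsets()] (or a
#'   numeric vector of onset times) used for artifact blanking.
#' @param blanking_s Blanking window after each onset, s; either a scalar or
#'   a named vector keyed by modality (e.g. `c(EStim = 2e-3, UStim = 0)`).
#' @param min_neg_ratio Minimum ratio of negative to positive lobe
#'   amplitude for a valid pairing.
#' @param dead_time Minimum separation between accepted events on one
#'   channel, s.
#' @param rel_floor Threshold floor as a fraction of the channel's maximum
#'   absolute value (guards the noiseless case where MAD is ~0).
#' @param saturation_v Absolute voltage at or above which an event is
#'   flagged saturated (kept, not dropped).
#' @param channels Channels to scan.
#' @return data.frame sorted by `t_pos_s` with columns `channel`, `t_pos_s`,
#'   `t_neg_s`, `amplitude_v`, `lobe_separation_s`, `quality`, `saturated`.
#'   Attributes `n_unpaired` (positive lobes with no matching negative
#'   lobe) and `suppressed` (diagnostics table of dead-time/blanking
#'   suppressions).
#' @export
detect_aps <- function(trace, threshold_k = 4, lobe_window = c(3e-4, 3e-3),
                       onsets = NULL, blanking_s = 2e-3,
                       min_neg_ratio = 0.4, dead_time = 3e-3,
                       rel_floor = 0.1, saturation_v = 2e-3,
                       channels = c("ch1", "ch2")) {
  stopifnot(inherits(trace, "recording_trace"), threshold_k > 0,
            length(lobe_window) == 2, lobe_window[1] < lobe_window[2])
  fs <- trace$sampling_rate
  onset_t <- NULL
  onset_blank <- NULL
  if (!is.null(onsets)) {
    if (is.data.frame(onsets)) {
      onset_t <- onsets$onset_s
      onset_blank <- if (length(blanking_s) > 1L) {
        b <- blanking_s[onsets$modality]
        b[is.na(b)] <- 0
        as.numeric(b)
      } else rep(blanking_s, length(onset_t))
    } else {
      onset_t <- as.numeric(onsets)
      onset_blank <- rep(blanking_s[1L], length(onset_t))
    }
  }

  res <- list()
  n_unpaired <- 0L
  suppressed <- list()
  for (ch in channels) {
    x <- trace$channels[[ch]]
    if (!length(x) || max(abs(x)) == 0) next
    thr <- max(threshold_k * stats::mad(x), rel_floor * max(abs(x)))
    cand <- .runs_argmax(x, thr)
    if (!length(cand)) next
    w_lo <- round(lobe_window[1] * fs)
    w_hi <- round(lobe_window[2] * fs)
    ev <- list()
    for (i in cand) {
      jw <- seq.int(min(i + w_lo, length(x)), min(i + w_hi, length(x)))
      j <- jw[which.min(x[jw])]
      if (x[j] > -min_neg_ratio * x[i]) { n_unpaired <- n_unpaired + 1L; next }
      rp <- .refine_peak(x, i)
      rn <- .refine_peak(x, j)
      ev[[length(ev) + 1L]] <- data.frame(
        channel = ch,
        t_pos_s = (i - 1L + rp[["offset"]]) / fs,
        t_neg_s = (j - 1L + rn[["offset"]]) / fs,
        amplitude_v = rp[["value"]],
        lobe_separation_s = (j - i + rn[["offset"]] - rp[["offset"]]) / fs,
        quality = rp[["value"]] / thr,
        saturated = max(abs(x[i:j])) >= saturation_v,
        stringsAsFactors = FALSE)
    }
    if (!length(ev)) next
    ev <- do.call(rbind, ev)
    # tie-break overlapping candidates: larger amplitude wins
    ev <- ev[order(ev$amplitude_v, decreasing = TRUE), , drop = FALSE]
    keep <- logical(nrow(ev))
    kept_t <- numeric()
    for (r in seq_len(nrow(ev))) {
      if (!length(kept_t) || all(abs(ev$t_pos_s[r] - kept_t) > dead_time)) {
        keep[r] <- TRUE
        kept_t <- c(kept_t, ev$t_pos_s[r])
      }
    }
    if (any(!keep))
      suppressed[[length(suppressed) + 1L]] <-
        cbind(ev[!keep, , drop = FALSE], reason = "dead_time")
    ev <- ev[keep, , drop = FALSE]
    # artifact blanking
    if (!is.null(onset_t) && nrow(ev)) {
      blanked <- vapply(ev$t_pos_s, function(t)
        any(t >= onset_t & t <= onset_t + onset_blank), logical(1))
      if (any(blanked))
        suppressed[[length(suppressed) + 1L]] <-
          cbind(ev[blanked, , drop = FALSE], reason = "blanking")
      ev <- ev[!blanked, , drop = FALSE]
    }
    res[[ch]] <- ev
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(channel = character(), t_pos_s = numeric(),
               t_neg_s = numeric(), amplitude_v = numeric(),
               lobe_separation_s = numeric(), quality = numeric(),
               saturated = logical(), stringsAsFactors = FALSE)
  out <- out[order(out$t_pos_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unpaired") <- n_unpaired
  attr(out, "suppressed") <- if (length(suppressed))
    do.call(rbind, suppressed) else NULL
  out
}
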