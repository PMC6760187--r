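#' Fiber model for a giant axon class
#'
#' Describes one of the two giant-fiber classes of the earthworm ventral
#' nerve cord: the Medial Giant Fiber (MGF, fast, large-amplitude) or the
#' Lateral Giant Fiber (LGF, slower, smaller-amplitude). The model carries
#' the conduction velocity and its per-AP jitter, the peak amplitude seen at
#' the recording electrodes, and the refractory period that bounds how
#' closely two APs of the same fiber may follow each other.
#'
#' @param fiber_class `"MGF"` or `"LGF"`.
#' @param conduction_velocity Conduction velocity in m/s (> 0).
#' @param velocity_jitter_sd Per-AP standard deviation of the instantaneous
#'   velocity, m/s.
#' @param peak_amplitude Nominal peak amplitude of one lobe of the biphasic
#'   waveform at the electrodes, volts.
#' @param amplitude_jitter_cv Coefficient of variation of the per-AP
#'   amplitude.
#' @param refractory_period Minimum same-fiber inter-AP interval, seconds.
#' @return An object of class `fiber_model`.
#' @export
fiber_model <- function(fiber_class = c("MGF", "LGF"),
                        conduction_velocity,
                        velocity_jitter_sd = 0,
                        peak_amplitude = 1e-3,
                        amplitude_jitter_cv = 0.05,
                        refractory_period = 4e-3) {
  fiber_class <- match.arg(fiber_class)
  stopifnot(is.finite(conduction_velocity), conduction_velocity > 0,
            is.finite(velocity_jitter_sd), velocity_jitter_sd >= 0,
            is.finite(peak_amplitude), peak_amplitude > 0,
            is.finite(amplitude_jitter_cv), amplitude_jitter_cv >= 0,
            is.finite(refractory_period), refractory_period > 0)
  structure(list(fiber_class = fiber_class,
                 conduction_velocity = conduction_velocity,
                 velocity_jitter_sd = velocity_jitter_sd,
                 peak_amplitude = peak_amplitude,
                 amplitude_jitter_cv = amplitude_jitter_cv,
                 refractory_period = refractory_period),
            class = "fiber_model")
}

#' Response model for one stimulation modality
#'
#' Captures how the preparation responds to one modality of stimulation
#' (EStim, MStim or UStim): which fiber class fires for a given stimulated
#' body region, the distribution of the time of generation (TOG), the
#' probability that a stimulus evokes any response (optionally a dose
#' response in the LEUS parameters), and the within-burst dynamics (expected
#' AP count, geometric adaptation across consecutive bursts, and the
#' multiplicative growth of the interval between successive APs).
#'
#' TOG is modelled log-normal: `tog_median` (seconds) fixes the median and
#' `tog_sdlog` the spread on the log scale, giving the non-negative,
#' right-skewed latencies seen across modalities. For EStim both fiber
#' classes respond, so `tog_median`/`tog_sdlog` may be named vectors with
#' entries `MGF` and `LGF`.
#'
#' @param modality `"EStim"`, `"MStim"` or `"UStim"`.
#' @param region Stimulated body region: `"anterior"` (recruits MGF),
#'   `"posterior"` (recruits LGF), `"medial"` (mostly silent), or `"both"`
#'   (EStim: both fibers regardless of region).
#' @param tog_median Median TOG in seconds (scalar, or named per fiber).
#' @param tog_sdlog Log-scale SD of the TOG distribution.
#' @param success_prob Baseline probability that one stimulus evokes a
#'   response, used when no dose model applies.
#' @param dose Optional list with logistic dose-response coefficients for
#'   UStim: `b0`, `b_logprf` (per log-Hz), `b_pa_mpa` (per MPa),
#'   `b_logdur_ms` (per log-ms) and `pa_floor_mpa`, a hard pressure floor
#'   below which no response is ever evoked.
#' @param ap_rate Expected number of APs per successful response at the
#'   reference condition (first burst of a train).
#' @param burst_adaptation Multiplicative decay of `ap_rate` per successive
#'   burst within a train (bursts separated by less than `adaptation_reset`).
#' @param interval_growth Multiplicative growth of the interval between
#'   successive APs within one response.
#' @param first_interval Interval between the first and second AP of a
#'   response, seconds; `NULL` means `max(1/PRF, refractory period)`.
#' @param adaptation_reset Rest duration (s) after which burst adaptation
#'   resets.
#' @param medial_attenuation Multiplier applied to the success probability
#'   when `region == "medial"`.
#' @return An object of class `response_model`.
#' @export
response_model <- function(modality = c("EStim", "MStim", "UStim"),
                           region = c("posterior", "anterior", "medial", "both"),
                           tog_median,
                           tog_sdlog,
                           success_prob = 1,
                           dose = NULL,
                           ap_rate = 1,
                           burst_adaptation = 0.7,
                           interval_growth = 1.3,
                           first_interval = NULL,
                           adaptation_reset = 1,
                           medial_attenuation = 0.15) {
  modality <- match.arg(modality)
  region <- match.arg(region)
  stopifnot(all(is.finite(tog_median)), all(tog_median > 0),
            all(is.finite(tog_sdlog)), all(tog_sdlog >= 0),
            is.finite(success_prob), success_prob >= 0, success_prob <= 1,
            is.finite(ap_rate), ap_rate >= 0,
            is.finite(burst_adaptation), burst_adaptation > 0, burst_adaptation <= 1,
            is.finite(interval_growth), interval_growth >= 1)
  if (!is.null(dose)) {
    needed <- c("b0", "b_logprf", "b_pa_mpa", "b_logdur_ms", "pa_floor_mpa")
    stopifnot(all(needed %in% names(dose)),
              all(vapply(dose[needed], is.finite, logical(1))),
              dose$b_logprf >= 0, dose$b_pa_mpa >= 0, dose$b_logdur_ms >= 0)
  }
  structure(list(modality = modality, region = region,
                 tog_median = tog_median, tog_sdlog = tog_sdlog,
                 success_prob = success_prob, dose = dose,
                 ap_rate = ap_rate, burst_adaptation = burst_adaptation,
                 interval_growth = interval_growth,
                 first_interval = first_interval,
                 adaptation_reset = adaptation_reset,
                 medial_attenuation = medial_attenuation),
            class = "response_model")
}

#' Electrode geometry of the recording montage
#'
#' Four electrodes aligned longitudinally, equally spaced. Each bipolar pair
#' is (anode, cathode) with the anode closer to the region of stimulation;
#' with the default 1 cm spacing the two anodes are 2 cm apart, twice the
#' anode-to-cathode separation.
#'
#' @param stim_to_first_anode Axonal distance from the point of stimulation
#'   to the first (closer) recording anode, metres.
#' @param electrode_spacing Spacing between adjacent electrodes, metres.
#' @return An object of class `electrode_geometry` with element
#'   `electrode_positions` (anode1, cathode1, anode2, cathode2 distances from
#'   the stimulation point), `anode_separation` and
#'   `anode_cathode_separation`.
#' @export
electrode_geometry <- function(stim_to_first_anode = 0.084,
                               electrode_spacing = 0.01) {
  stopifnot(is.finite(stim_to_first_anode), stim_to_first_anode > 0,
            is.finite(electrode_spacing), electrode_spacing > 0)
  pos <- stim_to_first_anode + electrode_spacing * 0:3
  names(pos) <- c("anode1", "cathode1", "anode2", "cathode2")
  structure(list(electrode_positions = pos,
                 anode_separation = 2 * electrode_spacing,
                 anode_cathode_separation = electrode_spacing,
                 stim_to_first_anode = stim_to_first_anode),
            class = "electrode_geometry")
}

#' Pulsed LEUS sequence specification
#'
#' One burst of pulsed low-energy ultrasound: `n_pulses` tone bursts of
#' `n_cycles` cycles at carrier frequency `f`, repeated at the pulse
#' repetition frequency `prf`. Pulse duration is `n_cycles / f` and the
#' pulse period is `1 / prf`.
#'
#' @param f Carrier frequency, Hz.
#' @param n_cycles Cycles per pulse.
#' @param prf Pulse repetition frequency, Hz.
#' @param n_pulses Pulses per burst.
#' @param p_a Peak pressure amplitude, Pa.
#' @param burst_onsets Optional vector of burst onset times, seconds.
#' @return An object of class `leus_sequence`.
#' @export
leus_sequence <- function(f = 1.1e6, n_cycles = 175, prf = 125,
                          n_pulses = 20, p_a = 6.6e6, burst_onsets = NULL) {
  stopifnot(f > 0, n_cycles > 0, prf > 0, n_pulses >= 1, p_a >= 0)
  structure(list(f = f, n_cycles = n_cycles, prf = prf,
                 n_pulses = n_pulses, p_a = p_a,
                 burst_onsets = burst_onsets),
            class = "leus_sequence")
}

#' One administered stimulus
#'
#' @param modality `"EStim"`, `"MStim"` or `"UStim"`.
#' @param onset Onset time, seconds (EStim pulse onset, MStim contact time,
#'   UStim burst onset).
#' @param leus For UStim, a [leus_sequence()] describing the burst.
#' @return An object of class `stimulus_event`.
#' @export
stimulus_event <- function(modality = c("EStim", "MStim", "UStim"),
                           onset, leus = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.finite(onset), onset >= 0)
  if (modality == "UStim" && is.null(leus)) leus <- leus_sequence()
  structure(list(modality = modality, onset = onset, leus = leus),
            class = "stimulus_event")
}

#' Build a regular single-modality protocol
#'
#' @param modality Stimulation modality.
#' @param n Number of stimuli.
#' @param start Onset of the first stimulus, s.
#' @param interval Inter-onset interval, s.
#' @param leus Optional [leus_sequence()] shared by all UStim stimuli.
#' @return A list of [stimulus_event()] objects with strictly increasing
#'   onsets.
#' @export
make_protocol <- function(modality, n, start = 0.2, interval = 0.25,
                          leus = NULL) {
  stopifnot(n >= 1, interval > 0)
  lapply(seq_len(n) - 1L, function(i)
    stimulus_event(modality, onset = start + i * interval, leus = leus))
}

#' Probability that one stimulus evokes a response
#'
#' For a model without a dose component this is the baseline
#' `success_prob`. For a UStim dose model the probability is a logistic in
#' `log(PRF)`, pressure amplitude (MPa) and `log(pulse duration in ms)`,
#' clamped to exactly zero below the hard pressure floor. The probability is
#' non-decreasing in each of PRF, pressure and pulse duration. Stimulation
#' of the medial region attenuates the probability by `medial_attenuation`.
#'
#' @param model A [response_model()].
#' @param prf Pulse repetition frequency, Hz.
#' @param p_a Pressure amplitude, Pa.
#' @param pulse_duration Pulse duration, seconds.
#' @return Probability in \[0, 1\].
#' @export
success_probability <- function(model, prf = NULL, p_a = NULL,
                                pulse_duration = NULL) {
  p <- model$success_prob
  if (!is.null(model$dose)) {
    stopifnot(!is.null(prf), !is.null(p_a), !is.null(pulse_duration),
              prf > 0, pulse_duration > 0, p_a >= 0)
    d <- model$dose
    if (p_a / 1e6 < d$pa_floor_mpa) return(0)
    eta <- d$b0 + d$b_logprf * log(prf) + d$b_pa_mpa * p_a / 1e6 +
      d$b_logdur_ms * log(pulse_duration * 1e3)
    p <- stats::plogis(eta)
  }
  if (model$region == "medial") p <- p * model$medial_attenuation
  p
}

#' Default models calibrated to the study preparation
#'
#' Returns the fiber models, per-modality response models and electrode
#' geometry whose defaults reproduce the preparation's headline numbers:
#' MGF conduction velocity 16.6 m/s and LGF 9.0 m/s; EStim evokes exactly
#' one AP in each fiber with short, nearly fixed TOGs (medians 1.3 ms MGF,
#' 2.4 ms LGF); MStim evokes a single fiber class (region-dependent) with a
#' long, variable TOG (median 33.0 ms, quartiles 26.1/36.6 ms); UStim
#' likewise single-class with an intermediate TOG (median 11.8 ms, quartiles
#' 11.2/13.1 ms) and a logistic dose response in PRF, pressure amplitude and
#' pulse duration with a hard 4.0 MPa floor. Log-scale spreads are fitted
#' from the printed quartiles, so EStim spread < UStim spread < MStim
#' spread.
#'
#' @return A list with elements `fibers` (named list of [fiber_model()]),
#'   `responses` (named list of [response_model()]) and `geometry`
#'   ([electrode_geometry()]).
#' @export
default_study_models <- function() {
  fibers <- list(
    MGF = fiber_model("MGF", conduction_velocity = 16.6,
                      velocity_jitter_sd = 0.22, peak_amplitude = 1.0e-3,
                      amplitude_jitter_cv = 0.05, refractory_period = 4e-3),
    LGF = fiber_model("LGF", conduction_velocity = 9.0,
                      velocity_jitter_sd = 0.07, peak_amplitude = 0.4e-3,
                      amplitude_jitter_cv = 0.05, refractory_period = 4e-3)
  )
  # log-scale spreads from printed quartiles: sdlog = log(q3/q1) / (2 * 0.6745)
  responses <- list(
    EStim = response_model("EStim", region = "both",
                           tog_median = c(MGF = 1.3e-3, LGF = 2.4e-3),
                           tog_sdlog = c(MGF = 0.012, LGF = 0.0316),
                           success_prob = 1, ap_rate = 1,
                           burst_adaptation = 1, interval_growth = 1),
    MStim = response_model("MStim", region = "posterior",
                           tog_median = 33.0e-3, tog_sdlog = 0.2507,
                           success_prob = 0.9, ap_rate = 2,
                           first_interval = 15e-3),
    UStim = response_model("UStim", region = "posterior",
                           tog_median = 11.8e-3, tog_sdlog = 0.1162,
                           dose = list(b0 = -5.89, b_logprf = 1.2,
                                       b_pa_mpa = 0.5, b_logdur_ms = 0.8,
                                       pa_floor_mpa = 4.0),
                           ap_rate = 3)
  )
  list(fibers = fibers, responses = responses,
       geometry = electrode_geometry(stim_to_first_anode = 0.084,
                                     electrode_spacing = 0.01))
}
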