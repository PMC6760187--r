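# Parametric experiment designs: randomized PRF comparison, amplitude x
# duration threshold mapping, and strength-duration summaries.

#' LEUS pulse/burst timing
#'
#' @param spec A [leus_sequence()].
#' @return List with `pulse_duration` (= N_cycles / f), `pulse_period`
#'   (= 1 / PRF) and `burst_duration`
#'   (= (N_pulses - 1) x period + duration), all in seconds.
#' @export
pulse_timing <- function(spec) {
  stopifnot(inherits(spec, "leus_sequence"))
  if (spec$f <= 0 || spec$prf <= 0 || spec$n_cycles <= 0 || spec$n_pulses < 1)
    stop("LEUS parameters must be positive")
  dur <- spec$n_cycles / spec$f
  period <- 1 / spec$prf
  list(pulse_duration = dur, pulse_period = period,
       burst_duration = (spec$n_pulses - 1) * period + dur)
}

# Abstract responder draw: number of APs evoked by one administered
# stimulus (0 = no response), using the same success/count laws as the
# trace generator but without rendering waveforms.
.draw_response <- function(model, leus = NULL, burst_index = 1L) {
  if (!is.null(model$dose)) {
    stopifnot(!is.null(leus))
    p <- success_probability(model, prf = leus$prf, p_a = leus$p_a,
                             pulse_duration = leus$n_cycles / leus$f)
  } else p <- success_probability(model)
  if (stats::runif(1) >= p) return(0L)
  lambda <- model$ap_rate * model$burst_adaptation^(burst_index - 1L)
  if (!is.null(leus)) lambda <- lambda * sqrt(leus$prf / 125)
  1L + stats::rpois(1, max(lambda - 1, 0))
}

#' Randomized factorial design for LEUS parametric studies
#'
#' @param prf_levels PRF levels to compare, Hz.
#' @param n_per_level Administered stimuli per level.
#' @param f Carrier frequency, Hz.
#' @param n_cycles Cycles per pulse.
#' @param p_a Pressure amplitude, Pa.
#' @param n_pulses Pulses per burst.
#' @param seed Randomization seed.
#' @return An object of class `parametric_design`.
#' @export
parametric_design <- function(prf_levels = c(125, 25), n_per_level = 20,
                              f = 1.1e6, n_cycles = 175, p_a = 6.6e6,
                              n_pulses = 20, seed = NULL) {
  stopifnot(all(prf_levels > 0), n_per_level >= 1, f > 0, n_cycles > 0,
            p_a > 0, n_pulses >= 1)
  structure(list(prf_levels = prf_levels, n_per_level = n_per_level,
                 f = f, n_cycles = n_cycles, p_a = p_a,
                 n_pulses = n_pulses, seed = seed),
            class = "parametric_design")
}

#' Randomized PRF comparison
#'
#' Administers `n_per_level` stimuli at each PRF level in randomized order
#' (a seeded permutation of the declared instances), all other LEUS
#' parameters shared between levels, and tabulates the success rate and the
#' full AP-count vector per level. AP counts include zeros for stimuli that
#' evoked no response.
#'
#' `responder` is either a [response_model()] (synthetic draws) or a
#' data.frame of real response records with columns `prf` and `ap_count`,
#' in which case the records are summarized as-is.
#'
#' @param design A [parametric_design()]; per-level LEUS parameters other
#'   than PRF must be identical (mismatches are a hard error).
#' @param responder Response model or response-record data.frame.
#' @param seed Overrides the design seed.
#' @return List with `summary` (one row per PRF: `prf`, `administered`,
#'   `responded`, `success_rate`), `ap_counts` (named list of per-level
#'   count vectors in administration order) and `instances` (the randomized
#'   administration table).
#' @export
run_prf_comparison <- function(design, responder, seed = design$seed) {
  stopifnot(inherits(design, "parametric_design"))
  if (length(unique(design$prf_levels)) < length(design$prf_levels))
    stop("duplicate PRF levels")
  if (length(design$f) > 1 || length(design$n_cycles) > 1 ||
      length(design$p_a) > 1 || length(design$n_pulses) > 1)
    stop("non-PRF parameters must be shared between levels")

  if (is.data.frame(responder)) {
    stopifnot(all(c("prf", "ap_count") %in% names(responder)))
    inst <- responder
  } else {
    stopifnot(inherits(responder, "response_model"))
    inst <- .with_seed(seed, function() {
      tab <- data.frame(prf = rep(design$prf_levels, each = design$n_per_level))
      tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
      tab$ap_count <- vapply(tab$prf, function(prf)
        .draw_response(responder,
                       leus_sequence(design$f, design$n_cycles, prf,
                                     design$n_pulses, design$p_a)),
        integer(1))
      rownames(tab) <- NULL
      tab
    })
  }
  lev <- sort(unique(inst$prf), decreasing = TRUE)
  summary <- do.call(rbind, lapply(lev, function(prf) {
    counts <- inst$ap_count[inst$prf == prf]
    data.frame(prf = prf, administered = length(counts),
               responded = sum(counts >= 1),
               success_rate = mean(counts >= 1))
  }))
  ap_counts <- lapply(stats::setNames(lev, paste0("prf_", lev)),
                      function(prf) inst$ap_count[inst$prf == prf])
  list(summary = summary, ap_counts = ap_counts, instances = inst)
}

#' Amplitude-by-duration threshold search
#'
#' For every pulse duration (ascending `n_cycles`), descends the declared
#' amplitude ladder administering more than `min_null_attempts` stimuli per
#' level (`min_null_attempts + 1`), and stops at the first amplitude that
#' evokes zero responses. Records, per duration, the minimal amplitude that
#' evoked at least one response and the maximal amplitude that never did.
#' The ladder is walked independently per duration.
#'
#' @param durations Pulse durations as cycles per pulse, ascending.
#' @param amplitudes Pressure amplitudes to test, Pa (any order; the search
#'   descends them).
#' @param responder A [response_model()] with a dose component.
#' @param f Carrier frequency, Hz.
#' @param prf Pulse repetition frequency, Hz.
#' @param n_pulses Pulses per burst.
#' @param min_null_attempts A level is declared null only after more than
#'   this many response-free stimuli.
#' @param seed Randomization seed.
#' @return List with `map` (per duration: `n_cycles`, `pulse_duration_s`,
#'   `min_responding_pa`, `null_pa`, `status` of `"ok"`,
#'   `"above_max_tested"` when even the largest amplitude never responded,
#'   or `"below_min_tested"` when every amplitude responded) and
#'   `administered` (every stimulus with its outcome).
#' @export
threshold_search <- function(durations, amplitudes, responder, f = 1.1e6,
                             prf = 125, n_pulses = 20,
                             min_null_attempts = 5, seed = NULL) {
  stopifnot(length(durations) >= 1, length(amplitudes) >= 1,
            all(durations > 0), all(amplitudes > 0),
            inherits(responder, "response_model"), min_null_attempts >= 1)
  durations <- sort(durations)
  amplitudes <- sort(amplitudes, decreasing = TRUE)
  n_att <- min_null_attempts + 1L
  .with_seed(seed, function() {
    rows <- list(); admin <- list()
    for (nc in durations) {
      min_resp <- NA_real_; null_pa <- NA_real_
      for (pa in amplitudes) {
        counts <- vapply(seq_len(n_att), function(i)
          .draw_response(responder,
                         leus_sequence(f, nc, prf, n_pulses, pa)),
          integer(1))
        admin[[length(admin) + 1L]] <- data.frame(
          n_cycles = nc, p_a = pa, attempt = seq_len(n_att),
          ap_count = counts, responded = counts >= 1)
        if (any(counts >= 1)) min_resp <- pa
        else { null_pa <- pa; break }
      }
      status <- if (is.na(min_resp)) "above_max_tested"
      else if (is.na(null_pa)) "below_min_tested"
      else "ok"
      rows[[length(rows) + 1L]] <- data.frame(
        n_cycles = nc, pulse_duration_s = nc / f,
        min_responding_pa = min_resp, null_pa = null_pa, status = status,
        stringsAsFactors = FALSE)
    }
    list(map = do.call(rbind, rows), administered = do.call(rbind, admin))
  })
}

#' Strength-duration summary
#'
#' Tabulates activation threshold against pulse duration (per fiber class
#' when a `fiber` column is present), reports whether each series is
#' non-increasing with duration, and whether the last two points differ by
#' less than a relative plateau tolerance (the hallmark of the
#' strength-duration plateau). With both classes present, also reports
#' whether the LGF threshold lies above the MGF threshold at every shared
#' duration.
#'
#' @param thresholds data.frame with columns `duration`, `threshold`, and
#'   optionally `fiber`.
#' @param plateau_tol Relative difference below which the last two
#'   thresholds count as a plateau.
#' @return List with `table` (ordered input), `per_class` (per fiber:
#'   `non_increasing`, `plateau`, `plateau_level`) and
#'   `lgf_above_mgf` (`NA` unless both classes are present).
#' @export
strength_duration_summary <- function(thresholds, plateau_tol = 0.05) {
  stopifnot(is.data.frame(thresholds),
            all(c("duration", "threshold") %in% names(thresholds)))
  if (!"fiber" %in% names(thresholds)) thresholds$fiber <- "all"
  thresholds <- thresholds[order(thresholds$fiber, thresholds$duration), ,
                           drop = FALSE]
  per_class <- do.call(rbind, lapply(split(thresholds, thresholds$fiber),
    function(d) {
      thr <- d$threshold
      if (length(thr) < 2)
        return(data.frame(fiber = d$fiber[1], non_increasing = NA,
                          plateau = NA, plateau_level = NA_real_,
                          stringsAsFactors = FALSE))
      last2 <- abs(thr[length(thr)] - thr[length(thr) - 1]) /
        abs(thr[length(thr)])
      data.frame(fiber = d$fiber[1],
                 non_increasing = all(diff(thr) <= 0),
                 plateau = last2 < plateau_tol,
                 plateau_level = if (last2 < plateau_tol)
                   thr[length(thr)] else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_class) <- NULL
  lgf_above_mgf <- NA
  if (all(c("MGF", "LGF") %in% thresholds$fiber)) {
    m <- thresholds[thresholds$fiber == "MGF", ]
    l <- thresholds[thresholds$fiber == "LGF", ]
    shared <- intersect(m$duration, l$duration)
    if (length(shared))
      lgf_above_mgf <- all(l$threshold[match(shared, l$duration)] >
                             m$threshold[match(shared, m$duration)])
  }
  list(table = thresholds, per_class = per_class,
       lgf_above_mgf = lgf_above_mgf)
}
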