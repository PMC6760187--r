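# Band-pass filtering and biphasic AP detection.

models <- default_study_models()

test_that("filter passes the analysis band and removes drift and DC", {
  fs <- 4e4
  t <- seq(0, 2, by = 1 / fs)
  mid <- 8000:72000  # away from edges
  f600 <- filter_signal(sin(2 * pi * 600 * t), fs)
  expect_equal(max(f600[mid]), 1, tolerance = 0.05)
  f10 <- filter_signal(sin(2 * pi * 10 * t), fs)
  expect_lt(max(abs(f10[mid])), 0.05)
  # independent FFT-based measurement of the realized frequency response
  set.seed(1)
  x <- rnorm(2^16)
  y <- filter_signal(x, fs)
  gain <- Mod(fft(y)) / Mod(fft(x))
  freq <- (seq_along(x) - 1) * fs / length(x)
  expect_gt(mean(gain[freq > 300 & freq < 900]), 0.9)
  expect_lt(mean(gain[freq > 5 & freq < 40]), 0.05)
  expect_lt(mean(gain[freq > 5000 & freq < 10000]), 0.05)
  # DC exactly removed
  expect_equal(mean(filter_signal(rep(3, fs), fs)), 0, tolerance = 1e-10)
})

test_that("zero-phase filtering does not shift a planted lobe peak", {
  fs <- 4e4
  x <- numeric(fs)  # 1 s
  t0 <- 0.5
  tt <- (seq_len(fs) - 1) / fs
  w <- 1.5e-3
  inw <- abs(tt - t0) < w / 2
  x[inw] <- 0.5 * (1 + cos(2 * pi * (tt[inw] - t0) / w))
  y <- filter_signal(x, fs)
  expect_lte(abs(which.max(y) - which.max(x)), 1)
})

test_that("filter rejects invalid band edges and too-short traces", {
  expect_error(filter_signal(rnorm(4e4), 4e4, low = 1200, high = 120))
  expect_error(filter_signal(rnorm(4e4), 4e4, high = 3e4))
  expect_error(filter_signal(rnorm(100), 4e4), "warm-up")
  tr <- recording_trace(2000, rnorm(4000), rnorm(4000), numeric(4000))
  expect_error(bandpass_filter(tr), "twice the high cutoff")
})

test_that("onset detection recovers planted stimuli exactly", {
  prot <- make_protocol("EStim", 20, start = 0.2, interval = 0.25)
  sim <- simulate_recording(prot, models$fibers, models$responses,
                            models$geometry, noise_sd = 0, seed = 5)
  on <- detect_stimulus_onsets(sim$trace)
  expect_equal(nrow(on), 20L)
  planted <- vapply(prot, `[[`, numeric(1), "onset")
  expect_true(all(abs(on$onset_s - planted) <= 1 / sim$trace$sampling_rate))
  expect_true(all(diff(on$onset_s) > 0))
})

test_that("flat artifact channel yields no onsets, with a count warning", {
  n <- 4e4
  tr <- recording_trace(4e4, numeric(n), numeric(n), numeric(n),
                        models$geometry,
                        protocol = make_protocol("EStim", 3))
  expect_warning(on <- detect_stimulus_onsets(tr), "declares 3")
  expect_equal(nrow(on), 0L)
})

test_that("two artifacts 10 ms apart resolve as two distinct onsets", {
  prot <- list(stimulus_event("EStim", 0.200),
               stimulus_event("EStim", 0.210))
  sim <- simulate_recording(prot, models$fibers, models$responses,
                            models$geometry, noise_sd = 0, seed = 1,
                            duration = 0.5)
  on <- detect_stimulus_onsets(sim$trace)
  expect_equal(nrow(on), 2L)
  expect_equal(on$onset_s, c(0.200, 0.210), tolerance = 1e-4)
})

test_that("noiseless planted APs are recovered exactly", {
  fib <- list(MGF = models$fibers$MGF)
  prot <- make_protocol("EStim", 5, start = 0.2, interval = 0.25)
  sim <- simulate_recording(prot, fib, fixed_mgf_responder(),
                            models$geometry, noise_sd = 0, seed = 2)
  filt <- bandpass_filter(sim$trace)
  ev <- detect_aps(filt, onsets = detect_stimulus_onsets(sim$trace))
  for (ch in c("ch1", "ch2")) {
    e <- ev[ev$channel == ch, ]
    expect_equal(nrow(e), 5L)  # conservation: one detection per log row
    truth <- sim$log[[if (ch == "ch1") "anode1_arrival_s" else
      "anode2_arrival_s"]]
    expect_true(all(abs(sort(e$t_pos_s) - sort(truth)) <=
                      1 / sim$trace$sampling_rate))
    expect_true(all(e$t_neg_s > e$t_pos_s))
    expect_true(all(e$lobe_separation_s > 3e-4 & e$lobe_separation_s < 3e-3))
  }
})

test_that("filter + detect is invariant to a constant offset", {
  prot <- make_protocol("EStim", 4, start = 0.2, interval = 0.25)
  sim <- simulate_recording(prot, models$fibers, models$responses,
                            models$geometry, noise_sd = 2e-5, seed = 9)
  ev0 <- detect_aps(bandpass_filter(sim$trace))
  shifted <- sim$trace
  shifted$channels$ch1 <- shifted$channels$ch1 + 0.5
  shifted$channels$ch2 <- shifted$channels$ch2 - 0.2
  ev1 <- detect_aps(bandpass_filter(shifted))
  expect_equal(ev0$t_pos_s, ev1$t_pos_s, tolerance = 1e-9)
  expect_equal(ev0$amplitude_v, ev1$amplitude_v, tolerance = 1e-6)
})

test_that("doubling the sampling rate moves peaks by less than 0.1 ms", {
  prot <- make_protocol("EStim", 4, start = 0.2, interval = 0.25)
  t40 <- simulate_recording(prot, models$fibers, models$responses,
                            models$geometry, noise_sd = 0, seed = 3,
                            sampling_rate = 4e4)
  t80 <- simulate_recording(prot, models$fibers, models$responses,
                            models$geometry, noise_sd = 0, seed = 3,
                            sampling_rate = 8e4)
  e40 <- detect_aps(bandpass_filter(t40$trace))
  e80 <- detect_aps(bandpass_filter(t80$trace))
  e40 <- e40[e40$channel == "ch1", ]; e80 <- e80[e80$channel == "ch1", ]
  expect_equal(nrow(e40), nrow(e80))
  expect_true(all(abs(sort(e40$t_pos_s) - sort(e80$t_pos_s)) < 1e-4))
})

test_that("no detection is reported inside a blanking window", {
  # short axonal distance so the AP lands 1.6 ms after onset, inside the
  # 2 ms blanking window
  geom <- electrode_geometry(stim_to_first_anode = 0.005)
  fib <- list(MGF = models$fibers$MGF)
  prot <- make_protocol("EStim", 5, start = 0.2, interval = 0.25)
  sim <- simulate_recording(prot, fib, fixed_mgf_responder(), geom,
                            noise_sd = 0, seed = 4)
  filt <- bandpass_filter(sim$trace)
  on <- detect_stimulus_onsets(sim$trace)
  ev <- detect_aps(filt, onsets = on, blanking_s = 2e-3)
  for (r in seq_len(nrow(ev)))
    expect_false(any(ev$t_pos_s[r] >= on$onset_s &
                       ev$t_pos_s[r] <= on$onset_s + 2e-3))
  # suppressions are recorded, not silently dropped
  expect_gt(nrow(attr(ev, "suppressed")), 0)
  # with blanking disabled the same APs are found
  ev2 <- detect_aps(filt, onsets = on, blanking_s = 0)
  expect_equal(nrow(ev2[ev2$channel == "ch1", ]), 5L)
})

test_that("saturated events are flagged, not dropped; empty trace is empty", {
  fib <- list(MGF = fiber_model("MGF", 16.6, 0, peak_amplitude = 5e-3))
  prot <- make_protocol("EStim", 3, start = 0.2, interval = 0.25)
  sim <- simulate_recording(prot, fib, fixed_mgf_responder(),
                            models$geometry, noise_sd = 0, seed = 1)
  ev <- detect_aps(bandpass_filter(sim$trace))
  expect_equal(nrow(ev[ev$channel == "ch1", ]), 3L)
  expect_true(all(ev$saturated))
  n <- 4e4
  flat <- recording_trace(4e4, numeric(n), numeric(n), numeric(n))
  expect_equal(nrow(detect_aps(flat)), 0L)
})
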