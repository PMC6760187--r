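# Synthetic recording generator: ground truth structure, determinism,
# arrival arithmetic, refractoriness, dose-response shape.

models <- default_study_models()

test_that("EStim protocol plants one MGF and one LGF AP per stimulus", {
  prot <- make_protocol("EStim", 10, start = 0.2, interval = 0.25)
  sim <- simulate_recording(prot, models$fibers, models$responses,
                            models$geometry, noise_sd = 0, seed = 1)
  expect_equal(nrow(sim$log), 20L)
  counts <- table(sim$log$stimulus_id, sim$log$fiber)
  expect_true(all(counts == 1L))
})

test_that("null responder yields artifacts only and an empty log", {
  silent <- response_model("MStim", region = "posterior",
                           tog_median = 33e-3, tog_sdlog = 0.25,
                           success_prob = 0)
  prot <- make_protocol("MStim", 5, start = 0.2, interval = 0.25)
  sim <- simulate_recording(prot, models$fibers, silent, models$geometry,
                            noise_sd = 0, seed = 1)
  expect_equal(nrow(sim$log), 0L)
  expect_true(all(sim$trace$channels$ch1 == 0))
  expect_true(all(sim$trace$channels$ch2 == 0))
  expect_gt(max(sim$trace$channels$artifact), 0)
})

test_that("planted anode arrival equals onset + TOG + distance/velocity", {
  # UStim at 8.1 m/s over 7.5 cm with TOG 11.8 ms: arrival delay must be
  # 11.8 ms + 9.26 ms (independent hand calculation: 0.075 / 8.1 s)
  fib <- list(LGF = fiber_model("LGF", 8.1, velocity_jitter_sd = 0,
                                peak_amplitude = 4e-4))
  resp <- response_model("UStim", region = "posterior",
                         tog_median = 11.8e-3, tog_sdlog = 0,
                         success_prob = 1, ap_rate = 1,
                         burst_adaptation = 1, interval_growth = 1)
  geom <- electrode_geometry(stim_to_first_anode = 0.075)
  prot <- make_protocol("UStim", 3, start = 0.2, interval = 0.3,
                        leus = leus_sequence())
  sim <- simulate_recording(prot, fib, resp, geom, noise_sd = 0, seed = 7)
  onsets <- vapply(prot, `[[`, numeric(1), "onset")
  expect_equal(sim$log$anode1_arrival_s - onsets,
               rep(11.8e-3 + 0.075 / 8.1, 3), tolerance = 1e-12)
  # the arrival identity holds for every log row of any simulation
  sim2 <- simulate_recording(make_protocol("EStim", 8), models$fibers,
                             models$responses, models$geometry,
                             noise_sd = 0, seed = 3)
  on2 <- vapply(sim2$trace$protocol, `[[`, numeric(1), "onset")
  expect_equal(sim2$log$anode1_arrival_s - on2[sim2$log$stimulus_id] -
                 sim2$log$tog_s,
               models$geometry$stim_to_first_anode / sim2$log$velocity_mps,
               tolerance = 1e-12)
})

test_that("identical seed and inputs give bitwise-identical output", {
  prot <- make_protocol("UStim", 5, leus = leus_sequence())
  a <- simulate_recording(prot, models$fibers, models$responses,
                          models$geometry, seed = 42)
  b <- simulate_recording(prot, models$fibers, models$responses,
                          models$geometry, seed = 42)
  expect_identical(a$trace$channels, b$trace$channels)
  expect_identical(a$log, b$log)
  c <- simulate_recording(prot, models$fibers, models$responses,
                          models$geometry, seed = 43)
  expect_false(identical(a$trace$channels, c$trace$channels))
})

test_that("stimulus artifacts carry the onset time reference", {
  fs <- 4e4
  for (mod in c("EStim", "MStim", "UStim")) {
    prot <- make_protocol(mod, 4, start = 0.2, interval = 0.3,
                          leus = if (mod == "UStim") leus_sequence())
    sim <- simulate_recording(prot, models$fibers, models$responses,
                              models$geometry, noise_sd = 0, seed = 1,
                              sampling_rate = fs)
    on <- detect_stimulus_onsets(sim$trace)
    expect_equal(nrow(on), 4L)
    planted <- vapply(prot, `[[`, numeric(1), "onset")
    expect_true(all(abs(on$onset_s - planted) <= 1 / fs))
  }
  # MStim: exactly one positive artifact peak per stimulus
  w <- render_stimulus_artifact(stimulus_event("MStim", 0.1), fs)
  expect_equal(sum(diff(sign(diff(w))) == -2), 1L)  # single local max
})

test_that("default study models reproduce the reported calibration", {
  f <- models$fibers
  expect_equal(f$MGF$conduction_velocity, 16.6)
  expect_equal(f$LGF$conduction_velocity, 9.0)
  expect_gt(f$MGF$conduction_velocity, f$LGF$conduction_velocity)
  # UStim TOG: median exact, quartiles within 5% of 11.2 / 13.1 ms (a
  # log-symmetric fit cannot match slightly asymmetric printed quartiles
  # exactly)
  u <- models$responses$UStim
  expect_equal(qlnorm(0.5, log(u$tog_median), u$tog_sdlog), 11.8e-3)
  expect_equal(qlnorm(0.25, log(u$tog_median), u$tog_sdlog), 11.2e-3,
               tolerance = 0.05)
  expect_equal(qlnorm(0.75, log(u$tog_median), u$tog_sdlog), 13.1e-3,
               tolerance = 0.05)
  # 10,000 seeded MStim TOG draws: sample median within 5% of 33.0 ms
  m <- models$responses$MStim
  set.seed(11)
  draws <- rlnorm(1e4, log(m$tog_median), m$tog_sdlog)
  expect_equal(median(draws), 33.0e-3, tolerance = 0.05)
  # spread ordering: EStim < UStim < MStim
  expect_lt(max(models$responses$EStim$tog_sdlog), u$tog_sdlog)
  expect_lt(u$tog_sdlog, m$tog_sdlog)
  # geometry: equally spaced electrodes, anodes twice the pair separation
  g <- models$geometry
  expect_equal(unname(diff(g$electrode_positions)), rep(0.01, 3))
  expect_equal(g$anode_separation, 2 * g$anode_cathode_separation)
})

test_that("success probability is monotone in PRF, pressure and duration", {
  u <- models$responses$UStim
  prfs <- c(10, 25, 50, 125, 250)
  pas <- c(2e6, 4e6, 5.2e6, 6.6e6, 7.3e6)
  durs <- c(175, 350, 800, 1150) / 1.1e6
  for (pa in pas) for (d in durs) {
    p <- vapply(prfs, function(x) success_probability(u, x, pa, d), 1)
    expect_true(all(diff(p) >= 0))
  }
  for (prf in prfs) for (d in durs) {
    p <- vapply(pas, function(x) success_probability(u, prf, x, d), 1)
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0 & p <= 1))
  }
  for (prf in prfs) for (pa in pas) {
    p <- vapply(durs, function(x) success_probability(u, prf, pa, x), 1)
    expect_true(all(diff(p) >= 0))
  }
  # hard floor: never a response below 4.0 MPa
  expect_identical(success_probability(u, 125, 3.99e6, 175 / 1.1e6), 0)
})

test_that("no two same-fiber APs violate the refractory period", {
  leus <- leus_sequence(prf = 125)
  for (seed in 1:5) {
    prot <- make_protocol("UStim", 12, start = 0.2, interval = 0.25,
                          leus = leus)
    sim <- simulate_recording(prot, models$fibers, models$responses,
                              models$geometry, seed = seed)
    if (nrow(sim$log) < 2) next
    on <- vapply(sim$trace$protocol, `[[`, numeric(1), "onset")
    gen <- on[sim$log$stimulus_id] + sim$log$tog_s
    for (cl in unique(sim$log$fiber)) {
      g <- sort(gen[sim$log$fiber == cl])
      if (length(g) > 1)
        expect_true(all(diff(g) >= models$fibers[[cl]]$refractory_period))
    }
  }
})

test_that("expected APs per burst is non-increasing across a burst train", {
  m <- models$responses$UStim
  lambda <- m$ap_rate * m$burst_adaptation^(0:9)
  expect_true(all(diff(lambda) <= 0))
  # realized: closely spaced bursts (same train) show decaying mean counts
  leus <- leus_sequence()
  set.seed(99)
  counts <- replicate(60, {
    prot <- make_protocol("UStim", 6, start = 0.1, interval = 0.2,
                          leus = leus)   # < adaptation_reset: one train
    sim <- simulate_recording(prot, models$fibers, models$responses,
                              models$geometry, noise_sd = 0,
                              seed = sample.int(1e6, 1))
    tabulate(sim$log$stimulus_id, 6)
  })
  m_counts <- rowMeans(counts)
  expect_gt(m_counts[1], m_counts[6])
})

test_that("degenerate inputs are rejected or flagged", {
  prot <- make_protocol("EStim", 3)
  bad_prot <- prot; bad_prot[[2]]$onset <- bad_prot[[1]]$onset
  expect_error(simulate_recording(bad_prot, models$fibers, models$responses,
                                  models$geometry, seed = 1),
               "strictly increasing")
  bad_fib <- models$fibers
  bad_fib$MGF$conduction_velocity <- NaN
  expect_error(simulate_recording(prot, bad_fib, models$responses,
                                  models$geometry, seed = 1), "non-finite")
  # colliding APs are flagged, not merged: two fibers with near-equal
  # velocities and equal TOGs arrive within one lobe width
  fib <- list(MGF = fiber_model("MGF", 16.6, 0, peak_amplitude = 1e-3),
              LGF = fiber_model("LGF", 16.59, 0, peak_amplitude = 4e-4))
  resp <- response_model("EStim", region = "both",
                         tog_median = c(MGF = 1.3e-3, LGF = 1.3e-3),
                         tog_sdlog = c(MGF = 0, LGF = 0), ap_rate = 1,
                         burst_adaptation = 1)
  expect_warning(
    sim <- simulate_recording(make_protocol("EStim", 2), fib, resp,
                              models$geometry, noise_sd = 0, seed = 1),
    "collision")
  expect_true(all(sim$log$overlap))
})

test_that("simulation respects the declared sampling preconditions", {
  prot <- make_protocol("EStim", 2)
  expect_error(simulate_recording(prot, models$fibers, models$responses,
                                  models$geometry, sampling_rate = 5e3,
                                  seed = 1))
  expect_error(simulate_recording(prot, models$fibers, models$responses,
                                  models$geometry, noise_sd = -1, seed = 1))
})
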