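# Coupled-oscillator generator: limiting cases, determinism, and the
# statistical contracts of the spike and stimulus generators.

test_that("uncoupled noiseless oscillators advance linearly at their natural frequency", {
  cfg <- synth_config(n_channels_per_region = 2, duration = 4,
                      natural_freqs = c(5, 8, 11, 14),
                      coupling = matrix(0, 4, 4), phase_noise_sd = 0,
                      seed = 7)
  phi <- simulate_phases(cfg)
  n <- ncol(phi)
  dt <- 1 / cfg$fs
  # phi(t) = phi(0) + omega t exactly, up to float accumulation
  for (i in 1:4) {
    slope <- (phi[i, n] - phi[i, 1]) / ((n - 1) * dt)
    expect_equal(slope, 2 * pi * cfg$natural_freqs[i], tolerance = 1e-10)
    expect_equal(diff(phi[i, ]), rep(2 * pi * cfg$natural_freqs[i] * dt,
                                     n - 1), tolerance = 1e-9)
  }
})

test_that("strong symmetric coupling locks equal-frequency oscillators (PLV -> 1)", {
  K <- matrix(c(0, 20, 20, 0), 2, 2)
  cfg <- synth_config(n_channels_per_region = 1, duration = 20,
                      natural_freqs = c(10, 10), coupling = K,
                      phase_noise_sd = 0, seed = 11)
  phi <- simulate_phases(cfg)
  # discard the transient while the phase difference relaxes to its
  # fixed point, then the difference is constant and PLV is 1
  post <- phi[, 2501:ncol(phi)]
  expect_equal(plv(post[1, ], post[2, ]), 1.0, tolerance = 0.01)
  d <- post[1, ] - post[2, ]
  expect_lt(max(abs(d - d[1])), 1e-6)
})

test_that("simulation is bit-reproducible for a given seed", {
  cfg <- tiny_config(duration = 5)
  expect_identical(simulate_phases(cfg), simulate_phases(cfg))
  r1 <- synth_recording(cfg, "CCI", "tactile", seed = 9)
  r2 <- synth_recording(cfg, "CCI", "tactile", seed = 9)
  expect_identical(r1$recording$lfp, r2$recording$lfp)
  expect_identical(lapply(r1$recording$spike_trains, `[[`, "timestamps"),
                   lapply(r2$recording$spike_trains, `[[`, "timestamps"))
  r3 <- synth_recording(cfg, "CCI", "tactile", seed = 10)
  expect_false(identical(r1$recording$lfp, r3$recording$lfp))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_channels_per_region = 1,
                            natural_freqs = c(10, 10),
                            coupling = matrix(c(0, 1, 2, 0), 2, 2)),
               class = "plvnet_bad_config")
  expect_error(synth_config(duration = -1), class = "plvnet_bad_config")
  expect_error(synth_config(n_channels_per_region = 1, fs = 40,
                            natural_freqs = c(10, 30)),
               class = "plvnet_bad_config")
  cfg <- tiny_config()
  expect_error(simulate_phases(cfg, dt = 1 / cfg$fs * 2),
               class = "plvnet_bad_config")
  cfg$phase_noise_sd <- NaN
  expect_error(simulate_phases(cfg), class = "plvnet_bad_config")
})

test_that("cosine readout is bounded, amplitude-linear, and phase-faithful", {
  # narrowband trajectory: mild phase diffusion keeps the cosine's analytic
  # phase faithful to the generating phase
  cfg <- synth_config(n_channels_per_region = 1, duration = 6,
                      natural_freqs = c(10, 12), amplitude = 1,
                      obs_noise_sd = 0, phase_noise_sd = 0.2,
                      coupling = matrix(0, 2, 2), seed = 3)
  phi <- simulate_phases(cfg)
  x <- synth_lfp(phi, cfg)
  expect_lte(max(abs(x)), 1)
  # doubling the amplitude doubles the RMS exactly when noiseless
  cfg2 <- cfg; cfg2$amplitude <- rep(2, 2)
  x2 <- synth_lfp(phi, cfg2)
  expect_equal(sqrt(mean(x2^2)) / sqrt(mean(x^2)), 2, tolerance = 1e-12)
  # analytic phase of the noiseless readout recovers the input phase
  n <- ncol(phi)
  core <- floor(0.1 * n):ceiling(0.9 * n)
  rec_ph <- analytic_phase(x[1, ], cfg$fs)$phases
  dphi <- Arg(exp(1i * (rec_ph - (phi[1, ] %% (2 * pi)))))
  expect_lt(max(abs(dphi[core])), 0.05)
})

test_that("constant-rate Poisson counts and zero-rate degenerate case behave", {
  st <- synth_spikes(20, duration = 100, seed = 5, fs = 500)
  expect_lt(abs(length(st$timestamps) - 2000), 3 * sqrt(2000))
  expect_true(all(diff(st$timestamps) >= 0.002))
  expect_length(synth_spikes(0, duration = 10, seed = 1)$timestamps, 0)
  expect_error(synth_spikes(600, duration = 1, seed = 1),
               class = "plvnet_bad_config")
})

test_that("doubling the rate profile doubles the mean count", {
  counts <- vapply(1:100, function(s) c(
    length(synth_spikes(10, duration = 20, seed = s)$timestamps),
    length(synth_spikes(20, duration = 20, seed = 1000 + s)$timestamps)),
    numeric(2))
  ratio <- mean(counts[2, ]) / mean(counts[1, ])
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("realised rate tracks the requested rate within 5% over 480 s", {
  for (r in c(8, 30, 60)) {
    st <- synth_spikes(r, duration = 480, seed = r, fs = 500)
    expect_equal(length(st$timestamps) / 480, r, tolerance = 0.05)
  }
})

test_that("stimulus schedule has the couplet structure", {
  sch <- synth_stimulus_schedule(10, seed = 2)
  expect_length(sch$first_pulse_times, 20)
  expect_length(schedule_pulses(sch), 40)
  d <- sch$second_pulse_times - sch$first_pulse_times
  expect_true(all(d >= 0.150 & d <= 0.250))
  expect_equal(diff(sch$first_pulse_times), rep(0.5, 19))
  expect_equal(sch$pulse_width, 0.005)
  expect_identical(sch, synth_stimulus_schedule(10, seed = 2))
  expect_error(synth_stimulus_schedule(0.3, seed = 1),
               class = "plvnet_bad_schedule")
})

test_that("condition presets cover the design and scale as configured", {
  tab <- condition_presets()
  expect_equal(nrow(tab), 8)
  expect_setequal(paste(tab$group, tab$condition),
                  paste(rep(c("CR", "CCI"), 4),
                        rep(c("rest", "tactile", "reac_rest",
                              "reac_tactile"), each = 2)))
  expect_true(all(tab$coupling_multiplier > 0 & tab$rate_multiplier > 0 &
                    tab$evoked_coupling_multiplier > 0))
  cfg <- tiny_config()
  id <- apply_condition(cfg, "CR", "rest")
  expect_equal(id$coupling, cfg$coupling)
  expect_equal(id$base_rates, cfg$base_rates)
  cr <- apply_condition(cfg, "CR", "reac_rest")
  expect_equal(cr$base_rates, cfg$base_rates * 1.43)
  cci <- apply_condition(cfg, "CCI", "reac_rest")
  expect_equal(cci$base_rates, cfg$base_rates * 1.93)
  expect_error(apply_condition(cfg, "CR", "nonsense"),
               class = "plvnet_bad_preset")
})

test_that("evoked rate gain is realised in tactile recordings", {
  cfg <- synth_config(n_channels_per_region = 1, duration = 60,
                      natural_freqs = c(10, 11), base_rates = c(20, 20),
                      stim_rate_gain = 2, seed = 5)
  ratios <- vapply(1:6, function(s) {
    tac <- synth_recording(cfg, "CR", "tactile", seed = s)$recording
    rest <- synth_recording(cfg, "CR", "rest", seed = 100 + s)$recording
    evoked_rate(tac$spike_trains[[1]], tac$schedule) /
      firing_rate(rest$spike_trains[[1]], c(0, 60))
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.25)
})
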