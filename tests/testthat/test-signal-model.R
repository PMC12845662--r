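test_that("viable envelopes are pulsatile at the pulse rate with exact amplitude", {
  prof <- embryo_profile("v", viable = TRUE, pulse_rate = 4, pulse_amplitude = 3.7)
  env <- generate_envelope(prof, rate = 100, duration = 10)

  expect_equal(max(env$value_mV) - min(env$value_mV), 3.7, tolerance = 1e-12)

  # dominant DFT bin at 4.0 Hz, by direct DFT over candidate frequencies
  freqs <- seq(0.1, 15, by = 0.1)
  mags <- vapply(freqs, function(f) direct_dft_mag(env$value_mV, f, 100), numeric(1))
  expect_equal(freqs[which.max(mags)], 4.0, tolerance = 1e-9)
})

test_that("zero pulse amplitude yields an all-zero envelope", {
  prof <- embryo_profile("z", viable = TRUE, pulse_amplitude = 0)
  env <- generate_envelope(prof, rate = 100, duration = 1)
  expect_true(all(env$value_mV == 0))
})

test_that("non-viable envelopes are bounded noise, reproducible, and aperiodic", {
  prof <- embryo_profile("nv", viable = FALSE, nonviable_amplitude = 0.4, seed = 7)
  env <- generate_envelope(prof, rate = 100, duration = 10)
  # brute-force extremum scan
  expect_lte(max(env$value_mV) - min(env$value_mV), 0.4 + 1e-12)

  env2 <- generate_envelope(prof, rate = 100, duration = 10)
  expect_identical(env$value_mV, env2$value_mV)

  # different seeds differ (no deterministic component)
  env3 <- generate_envelope(prof, rate = 100, duration = 10, seed = 8)
  expect_false(isTRUE(all.equal(env$value_mV, env3$value_mV)))
})

test_that("envelope generation validates its arguments", {
  prof <- embryo_profile()
  expect_error(generate_envelope(prof, rate = -1), "positive")
  expect_error(generate_envelope(prof, duration = 0), "positive")
  expect_error(embryo_profile(pulse_rate = 0), "positive")
})

test_that("modulation produces the carrier model exactly in degenerate cases", {
  rate <- 100
  env <- ppg_trace(rep(0, rate * 1), rate, "envelope")
  cfg <- sim_config(
    duration = 1, phase = 0.3, mains_amplitude = 0,
    ambient_drift_amplitude = 0, white_noise_rms = 0
  )
  raw <- modulate(env, cfg)
  n <- seq_len(nrow(raw)) - 1
  expected <- 10 * sin(2 * pi * 2000 / 96000 * n + 0.3)
  expect_equal(raw$value_mV, expected, tolerance = 1e-12)

  # constant envelope c -> tone of amplitude carrier_bias + c
  envc <- ppg_trace(rep(2.5, rate * 1), rate, "envelope")
  rawc <- modulate(envc, cfg)
  expect_equal(rawc$value_mV, 12.5 / 10 * expected, tolerance = 1e-12)
})

test_that("overmodulation is rejected", {
  env <- ppg_trace(rep(-11, 200), 100, "envelope")
  cfg <- sim_config(duration = 2, ambient_drift_amplitude = 0)
  expect_error(modulate(env, cfg), "overmodulation")
})

test_that("demodulation round-trips the simulated envelope within 5% RMS", {
  prof <- embryo_profile("v", viable = TRUE, seed = 3)
  env <- generate_envelope(prof, rate = 100, duration = 10)
  # default sensor noise and mains on; drift off so the stored ground truth
  # is the full amplitude-domain content
  cfg <- sim_config(seed = 3, ambient_drift_amplitude = 0)
  raw <- modulate(env, cfg)
  rec <- demodulate(raw)
  resid <- rec$value_mV - cfg$carrier_bias - env$value_mV
  rel_rms <- sqrt(mean(resid^2)) / sqrt(mean(env$value_mV^2))
  expect_lt(rel_rms, 0.05)
})

test_that("simulate_batch returns labelled, deterministic batches", {
  cfg <- fast_config(duration = 2)
  b <- simulate_batch(15, 5, "c", cfg, seed = 1)
  expect_equal(nrow(b), 20)
  expect_equal(sum(b$viable), 15)

  b2 <- simulate_batch(15, 5, "c", cfg, seed = 1)
  expect_identical(b$trace[[7]]$value_mV, b2$trace[[7]]$value_mV)
  expect_identical(b$trace[[18]]$value_mV, b2$trace[[18]]$value_mV)

  empty <- simulate_batch(0, 0, "c", cfg, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(simulate_batch(-1, 0, "c", cfg), "non-negative")
})

test_that("no generated trace is overmodulated and labels separate in ground truth", {
  cfg <- fast_config(duration = 2)
  for (s in 1:5) {
    b <- simulate_batch(3, 2, "c", cfg, seed = s)
    v_pp <- vapply(b$envelope[b$viable], function(e) max(e$value_mV) - min(e$value_mV), numeric(1))
    nv_pp <- vapply(b$envelope[!b$viable], function(e) max(e$value_mV) - min(e$value_mV), numeric(1))
    expect_true(min(v_pp) >= 1)
    expect_true(max(nv_pp) <= 0.4)
    # reconstruct instantaneous carrier amplitude: min over windows must be > 0
    for (tr in b$trace) {
      refs <- make_references(2000, 96000, 20)
      env <- demodulate(tr, refs)
      expect_true(all(env$value_mV > 0))
    }
  }
})

test_that("arrangement presets respect the reported orderings", {
  a <- arrangement_preset("a")
  b <- arrangement_preset("b")
  c <- arrangement_preset("c")
  expect_true(b$amplitude_scale > c$amplitude_scale)
  expect_true(c$amplitude_scale > a$amplitude_scale)
  expect_true(b$lowband_noise_rms > c$lowband_noise_rms)
  expect_true(c$lowband_noise_rms >= a$lowband_noise_rms)
})

test_that("multi-day trend is unimodal with its maximum exactly at peak_day", {
  expect_equal(day_trend(12, peak_day = 12), 1.0)
  for (pk in 11:13) {
    days <- 10:14
    amp <- day_trend(days, peak_day = pk)
    expect_equal(days[which.max(amp)], pk)
    # exhaustive pairwise comparison on both flanks
    rising <- days[days <= pk]
    falling <- days[days >= pk]
    if (length(rising) > 1) expect_true(all(diff(amp[days %in% rising]) > 0))
    if (length(falling) > 1) expect_true(all(diff(amp[days %in% falling]) < 0))
  }
})

test_that("simulate_multiday scales amplitude by the trend and stays pulsatile", {
  prof <- embryo_profile("m", viable = TRUE, peak_day = 12, seed = 5)
  cfg <- fast_config(duration = 2)
  md <- simulate_multiday(prof, 10:14, cfg)
  expect_equal(md$day, 10:14)
  expect_equal(which.max(md$amplitude_mV), 3) # day 12
  pps <- vapply(md$envelope, function(e) max(e$value_mV) - min(e$value_mV), numeric(1))
  expect_equal(pps, md$amplitude_mV, tolerance = 1e-9)
  expect_error(simulate_multiday(prof, integer(0), cfg), "non-empty")
})
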