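test_that("threshold containers validate the amplitude gap", {
  expect_error(viability_thresholds(amplitude_min = 0.4), "strictly between")
  expect_error(viability_thresholds(amplitude_min = 1.0), "strictly between")
  expect_silent(viability_thresholds(amplitude_min = 0.5))
})

test_that("a noiseless pure sinusoid scores near-perfect periodicity", {
  tr <- tone_trace(4, 100, 10, amplitude = 1, kind = "processed")
  f <- extract_features(tr)
  expect_gte(f$periodicity, 0.95)
  expect_equal(f$peak_freq_Hz, 4, tolerance = 100 / 256)
  # no processing stages logged -> gain 1: peak-to-peak equals the sampled
  # extremes exactly (slightly under 2 since samples straddle the crests)
  expect_equal(f$peak_to_peak_mV, max(tr$value_mV) - min(tr$value_mV), tolerance = 1e-12)
  expect_equal(f$peak_to_peak_mV, 2, tolerance = 5e-3)
})

test_that("features separate simulated viable and non-viable embryos", {
  cfg <- sim_config(seed = 1)
  b <- simulate_batch(2, 2, "c", cfg, seed = 1)
  feats <- lapply(b$trace, function(tr) extract_features(preprocess(demodulate(tr))))

  for (i in which(b$viable)) {
    expect_equal(feats[[i]]$peak_freq_Hz, b$pulse_rate[i], tolerance = 0.5)
    expect_gte(feats[[i]]$peak_to_peak_mV, 1)
  }
  for (i in which(!b$viable)) {
    expect_lte(feats[[i]]$peak_to_peak_mV, 0.4)
  }
})

test_that("the four-criterion rule labels constructed feature rows correctly", {
  thr <- viability_thresholds()
  viable_row <- tibble::tibble(
    peak_freq_Hz = 4, peak_to_peak_mV = 3.7, concentration = 0.9, periodicity = 0.95
  )
  call <- classify_viability(viable_row, thr)
  expect_equal(as.character(call$label), "viable")
  expect_true(all(unlist(call[, c(
    "amplitude_ok", "frequency_ok",
    "concentration_ok", "periodicity_ok"
  )])))

  zero_amp <- viable_row
  zero_amp$peak_to_peak_mV <- 0
  expect_equal(as.character(classify_viability(zero_amp, thr)$label), "nonviable")

  wrong_freq <- viable_row
  wrong_freq$peak_to_peak_mV <- 2
  wrong_freq$peak_freq_Hz <- 12
  c2 <- classify_viability(wrong_freq, thr)
  expect_equal(as.character(c2$label), "nonviable")
  expect_true(c2$amplitude_ok)
  expect_false(c2$frequency_ok)

  bad <- viable_row
  bad$concentration <- NaN
  expect_error(classify_viability(bad, thr), "finite")
})

test_that("any amplitude threshold inside the printed gap gives identical calls", {
  cfg <- sim_config(seed = 2)
  b <- simulate_batch(3, 2, "c", cfg, seed = 2)
  feats <- purrr::list_rbind(
    lapply(b$trace, function(tr) extract_features(preprocess(demodulate(tr))))
  )
  labels <- lapply(c(0.45, 0.6, 0.7, 0.85, 0.95), function(amin) {
    purrr::list_rbind(lapply(seq_len(nrow(feats)), function(i) {
      classify_viability(feats[i, ], viability_thresholds(amplitude_min = amin))
    }))$label
  })
  for (k in 2:length(labels)) expect_identical(labels[[k]], labels[[1]])
})

test_that("batch evaluation computes the confusion summary and validates inputs", {
  calls <- tibble::tibble(
    embryo_id = sprintf("e%d", 1:20),
    label = factor(rep(c("viable", "nonviable"), c(15, 5)),
      levels = c("viable", "nonviable")
    )
  )
  truth <- tibble::tibble(embryo_id = sprintf("e%d", 1:20), viable = rep(c(TRUE, FALSE), c(15, 5)))
  ev <- evaluate_batch(calls, truth)
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(glance(ev)$tp, 15)
  expect_equal(nrow(tidy(ev)), 20)

  expect_error(evaluate_batch(calls[0, ], truth), "empty")
  expect_error(evaluate_batch(calls, truth[1:10, ]), "same embryo ids")

  # random labels vs random truth: accuracy near 50%
  withr::with_seed(1, {
    n <- 4000
    rc <- tibble::tibble(
      embryo_id = sprintf("r%d", 1:n),
      label = factor(sample(c("viable", "nonviable"), n, replace = TRUE),
        levels = c("viable", "nonviable")
      )
    )
    rt <- tibble::tibble(embryo_id = sprintf("r%d", 1:n), viable = sample(c(TRUE, FALSE), n, replace = TRUE))
  })
  acc <- evaluate_batch(rc, rt)$accuracy
  expect_lt(abs(acc - 50), 3 * 50 / sqrt(4000) + 1)
})

test_that("capture is a weaker criterion than viability and flags missing cells", {
  thr <- viability_thresholds()
  # weak but pulsatile: fails the amplitude criterion, still captured
  res <- tibble::tibble(
    embryo_id = rep(c("a", "b"), each = 2), day = rep(10:11, 2),
    periodicity = c(0.9, 0.9, 0.9, 0.9), peak_freq_Hz = 4,
    peak_to_peak_mV = 0.5, concentration = 0.9
  )
  weak_call <- classify_viability(res[1, c(
    "peak_freq_Hz", "peak_to_peak_mV",
    "concentration", "periodicity"
  )], thr)
  expect_equal(as.character(weak_call$label), "nonviable")

  cap <- assess_capture(res, thr)
  expect_equal(cap$success_rate, 100)
  expect_equal(cap$n_cells, 4)

  # drop one cell: recorded FALSE with a warning
  expect_warning(cap2 <- assess_capture(res[-4, ], thr, days = 10:11), "missing")
  expect_equal(sum(tidy(cap2)$captured), 3)
  expect_equal(cap2$success_rate, 75)
  expect_equal(glance(cap2)$n_captured, 3)
})

test_that("accuracy does not improve as sensor noise grows", {
  acc_at <- function(rms) {
    mean(vapply(1:2, function(s) {
      cfg <- sim_config(duration = 4, white_noise_rms = rms, seed = s)
      b <- simulate_batch(3, 2, "c", cfg, seed = s)
      glance(screen_batch(b))$accuracy
    }, numeric(1)))
  }
  lo <- acc_at(0.5)
  hi <- acc_at(150)
  expect_gte(lo, hi)
  expect_equal(lo, 100)
})
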