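test_that("stft frames match a direct DFT oracle and count correctly", {
  tr <- tone_trace(4, 100, 4)
  map <- stft(tr, window_length = 255, hop = 16)
  expect_equal(nrow(map$magnitudes), floor((400 - 255) / 16) + 1)
  expect_equal(ncol(map$magnitudes), 129)
  expect_equal(map$freqs[2] - map$freqs[1], 100 / 256)

  # oracle: direct DFT of two windowed frames
  w <- hann_window(255)
  for (fr in c(1, 5)) {
    s <- (fr - 1) * 16 + 1
    frame <- trace_values(tr)[s:(s + 254)] * w
    expect_equal(
      map$magnitudes[fr, ],
      direct_frame_mags(frame, 256, 100),
      tolerance = 1e-8
    )
  }
  # every frame's argmax bin is the bin nearest 4 Hz
  argmax_f <- map$freqs[apply(map$magnitudes[, map$freqs > 0.5], 1, which.max) + sum(map$freqs <= 0.5)]
  expect_true(all(abs(argmax_f - 4) <= 100 / 256 / 2 + 1e-9))
})

test_that("an all-zero trace maps to an all-zero spectrogram", {
  tr <- ppg_trace(numeric(400), 100, "processed")
  map <- stft(tr)
  expect_true(all(map$magnitudes == 0))
})

test_that("per-frame energy obeys Parseval's identity", {
  withr::with_seed(9, x <- rnorm(500))
  tr <- ppg_trace(x, 100, "processed")
  map <- stft(tr, hop = 64)
  w <- hann_window(255)
  for (fr in seq_len(nrow(map$magnitudes))) {
    s <- (fr - 1) * 64 + 1
    frame_energy <- sum((x[s:(s + 254)] * w)^2)
    m <- map$magnitudes[fr, ]
    twosided <- m[1]^2 + 2 * sum(m[2:128]^2) + m[129]^2
    expect_equal(twosided / 256, frame_energy, tolerance = 1e-6)
  }
})

test_that("delaying the input shifts frames without changing interior magnitudes", {
  withr::with_seed(4, x <- rnorm(600))
  hop <- 8
  tr1 <- ppg_trace(x, 100, "processed")
  tr2 <- ppg_trace(c(numeric(2 * hop), x), 100, "processed")
  m1 <- stft(tr1, hop = hop)
  m2 <- stft(tr2, hop = hop)
  n1 <- nrow(m1$magnitudes)
  expect_equal(
    m2$magnitudes[2 + seq_len(n1), ],
    m1$magnitudes,
    tolerance = 1e-9
  )
})

test_that("a tone at an exact bin concentrates its energy in three bins", {
  fbin <- 10 * 100 / 256 # exact bin frequency
  tr <- tone_trace(fbin, 100, 6)
  map <- stft(tr, hop = 32)
  for (fr in seq_len(nrow(map$magnitudes))) {
    e <- map$magnitudes[fr, ]^2
    expect_gt(sum(e[10:12]) / sum(e), 0.85)
  }
})

test_that("dominant frequency picks the time-averaged peak and breaks ties low", {
  tr <- tone_trace(4, 100, 6)
  map <- stft(tr, hop = 8)
  expect_equal(dominant_frequency(map), 4, tolerance = 100 / 256 / 2)

  # synthetic map with exactly equal peaks at 3 and 5 Hz
  fake <- map
  fake$magnitudes <- matrix(0, 4, length(map$freqs))
  i3 <- which.min(abs(map$freqs - 3))
  i5 <- which.min(abs(map$freqs - 5))
  fake$magnitudes[, c(i3, i5)] <- 1
  expect_equal(dominant_frequency(fake), map$freqs[i3])

  expect_error(dominant_frequency(map, c(5, 5)), "increasing")
  expect_error(stft(tone_trace(4, 100, 1)), "shorter")
})

test_that("white-noise dominant frequency matches a brute-force periodogram oracle", {
  withr::with_seed(13, x <- rnorm(500))
  tr <- ppg_trace(x, 100, "processed")
  map <- stft(tr, hop = 8)
  # independent oracle: direct per-frame DFT, same framing, averaged
  w <- hann_window(255)
  starts <- seq(1, 500 - 255 + 1, by = 8)
  acc <- numeric(129)
  for (s in starts) {
    acc <- acc + direct_frame_mags(x[s:(s + 254)] * w, 256, 100)
  }
  sel <- map$freqs >= 1 & map$freqs <= 15
  oracle_f <- map$freqs[sel][which.max((acc / length(starts))[sel])]
  expect_equal(dominant_frequency(map, c(1, 15)), oracle_f)
})

test_that("spectral concentration is high for tones, uniform-share for noise, 0 for silence", {
  tr <- tone_trace(4, 100, 8)
  map <- stft(tr, hop = 8)
  expect_gt(spectral_concentration(map, 4, 1), 0.9)

  # white noise: expected share = (# bins in band) / (# bins in denominator)
  ratios <- vapply(1:5, function(s) {
    withr::with_seed(s, xn <- rnorm(800))
    mn <- stft(ppg_trace(xn, 100, "processed"), hop = 8)
    spectral_concentration(mn, 6, 1)
  }, numeric(1))
  nb <- function(lo, hi) sum(seq(0, 50, by = 100 / 256) >= lo & seq(0, 50, by = 100 / 256) <= hi)
  expected <- nb(5, 7) / nb(0.5, 15)
  expect_equal(mean(ratios), expected, tolerance = 0.35)

  zmap <- stft(ppg_trace(numeric(400), 100, "processed"), hop = 8)
  expect_warning(r0 <- spectral_concentration(zmap, 4, 1), "no energy")
  expect_equal(r0, 0)

  expect_error(spectral_concentration(map, 0.5, 1), "beyond")
  expect_error(spectral_concentration(map, 4, 0), "positive")
})
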