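#' Ground-truth embryo profile
#'
#' Generative parameters for one embryo. A viable embryo carries a
#' deterministic pulsatile envelope (fundamental near 4 Hz plus low-order
#' harmonics); a non-viable embryo produces only aperiodic band-limited
#' fluctuations whose peak-to-peak amplitude never exceeds
#' `nonviable_amplitude`.
#'
#' @param embryo_id character identifier.
#' @param viable logical.
#' @param pulse_rate pulse fundamental frequency, Hz. Embryonic PPG
#'   signals cluster near 4 Hz at day 10-14.
#' @param pulse_amplitude peak-to-peak envelope amplitude in mV for a
#'   viable embryo (3.7 mV is the mean for source-detector arrangement "c").
#' @param nonviable_amplitude maximum peak-to-peak amplitude in mV of the
#'   residual fluctuations of a non-viable embryo.
#' @param peak_day incubation day at which the multi-day amplitude trend
#'   is maximal (cardiovascular maturation peaks near day 12, after which
#'   growing tissue attenuates the optical path).
#' @param harmonics relative amplitudes of the pulse harmonics, starting
#'   at the fundamental. The default `c(1, 0.25)` adds a second harmonic
#'   at 25% to give the waveform PPG-like asymmetry.
#' @param seed integer seed for any stochastic component.
#' @return A list of class `embryo_profile`.
#' @export
embryo_profile <- function(embryo_id = "e1", viable = TRUE, pulse_rate = 4,
                           pulse_amplitude = 3.7, nonviable_amplitude = 0.4,
                           peak_day = 12L, harmonics = c(1, 0.25), seed = 1L) {
  if (pulse_rate <= 0) abort("`pulse_rate` must be positive.")
  if (pulse_amplitude < 0) abort("`pulse_amplitude` must be >= 0.")
  if (nonviable_amplitude < 0) abort("`nonviable_amplitude` must be >= 0.")
  structure(
    list(
      embryo_id = as.character(embryo_id), viable = isTRUE(viable),
      pulse_rate = pulse_rate, pulse_amplitude = pulse_amplitude,
      nonviable_amplitude = nonviable_amplitude, peak_day = as.integer(peak_day),
      harmonics = harmonics, seed = as.integer(seed)
    ),
    class = "embryo_profile"
  )
}

#' Source-detector arrangement presets
#'
#' Amplitude and noise signatures of the three source-detector
#' geometries: (a) trans-illumination along the long axis (lowest
#' amplitude, least noise), (b) near-reflection mode (highest amplitude,
#' broadband 0-15 Hz noise), (c) 90-degree geometry (amplitude close to
#' (b), intermediate noise, with a well-defined high-frequency component
#' that the 7 Hz low-pass removes). Only the reported signal signatures
#' are emulated; no optics is computed.
#'
#' @param name `"a"`, `"b"` or `"c"` (the default, used in all the
#'   discrimination and monitoring experiments).
#' @return A list of class `arrangement_preset` with fields
#'   `amplitude_scale` (mean viable peak-to-peak, mV), `lowband_noise_rms`
#'   (broadband 0-15 Hz envelope noise, mV RMS) and `highband_noise_rms`
#'   (envelope noise above 7 Hz, mV RMS; realized as a well-defined 12 Hz
#'   component for arrangement "c").
#' @export
arrangement_preset <- function(name = c("c", "a", "b")) {
  name <- match.arg(name)
  p <- switch(name,
    a = list(amplitude_scale = 1.0, lowband_noise_rms = 0.02, highband_noise_rms = 0.02),
    b = list(amplitude_scale = 4.5, lowband_noise_rms = 0.50, highband_noise_rms = 0.30),
    c = list(amplitude_scale = 3.7, lowband_noise_rms = 0.04, highband_noise_rms = 0.15)
  )
  structure(c(list(name = name), p), class = "arrangement_preset")
}

#' Acquisition configuration
#'
#' Parameters of one simulated acquisition: the optical carrier, the raw
#' digitization, and the interference terms. The carrier at 2 kHz rides
#' well above ambient-light fluctuations (<= 200 Hz); digitization at
#' 96 kHz gives 48 samples per carrier cycle.
#'
#' @param fs_raw raw sampling rate, Hz.
#' @param f_carrier optical modulation (carrier) frequency, Hz.
#' @param duration acquisition length, seconds.
#' @param carrier_bias static-attenuation amplitude in mV on which the
#'   pulsatile envelope rides; must exceed the envelope excursion so the
#'   instantaneous carrier amplitude stays positive.
#' @param phase carrier phase in radians, or `NULL` to draw it from `seed`.
#' @param mains_freq,mains_amplitude power-line tone injected additively
#'   into the raw trace (Hz, mV).
#' @param ambient_drift_amplitude,ambient_drift_max_freq slow baseline
#'   drift of the received light level: three seeded sinusoids with
#'   frequencies below `ambient_drift_max_freq` plus a Gaussian random
#'   walk, scaled to `ambient_drift_amplitude` mV peak, applied in the
#'   amplitude (envelope) domain so it survives demodulation — this is
#'   the component the baseline-suppression stage removes.
#' @param white_noise_rms additive white sensor noise in the raw trace, mV RMS.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs_raw = 96000, f_carrier = 2000, duration = 10,
                       carrier_bias = 10, phase = NULL,
                       mains_freq = 50, mains_amplitude = 1,
                       ambient_drift_amplitude = 2, ambient_drift_max_freq = 0.5,
                       white_noise_rms = 0.5, seed = 1L) {
  if (fs_raw < 2 * f_carrier) abort("`fs_raw` must be at least twice `f_carrier`.")
  if (duration <= 0) abort("`duration` must be positive.")
  if (carrier_bias <= 0) abort("`carrier_bias` must be positive.")
  structure(
    list(
      fs_raw = fs_raw, f_carrier = f_carrier, duration = duration,
      carrier_bias = carrier_bias, phase = phase,
      mains_freq = mains_freq, mains_amplitude = mains_amplitude,
      ambient_drift_amplitude = ambient_drift_amplitude,
      ambient_drift_max_freq = ambient_drift_max_freq,
      white_noise_rms = white_noise_rms, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate a ground-truth PPG envelope
#'
#' Viable profiles yield a deterministic pulsatile waveform (fundamental
#' at `pulse_rate` plus the profile's harmonics) scaled so its
#' peak-to-peak amplitude equals `pulse_amplitude`. Non-viable profiles
#' yield seeded band-limited (0-7 Hz) noise scaled so its peak-to-peak
#' amplitude equals `nonviable_amplitude`. The same `(profile, seed)`
#' reproduces identical output.
#'
#' @param profile an [embryo_profile()].
#' @param rate envelope sampling rate, Hz (default 100; one sample per
#'   20-cycle demodulation window at the 96 kHz / 2 kHz defaults).
#' @param duration seconds.
#' @param seed integer; defaults to the profile's seed.
#' @return An envelope [ppg_trace()] whose `meta$profile` stores the
#'   generative ground truth.
#' @export
generate_envelope <- function(profile, rate = 100, duration = 10,
                              seed = profile$seed) {
  if (!inherits(profile, "embryo_profile")) abort("`profile` must be an embryo_profile.")
  if (duration <= 0 || rate <= 0) abort("`duration` and `rate` must be positive.")
  n <- round(duration * rate)
  if (n < 2) abort("`duration * rate` must be at least 2 samples.")
  t <- (seq_len(n) - 1) / rate
  if (profile$viable) {
    h <- profile$harmonics
    w <- rep(0, n)
    for (k in seq_along(h)) {
      w <- w + h[k] * sin(2 * pi * k * profile$pulse_rate * t + (k - 1) * pi / 3)
    }
    pp <- max(w) - min(w)
    env <- if (pp > 0) w / pp * profile$pulse_amplitude else w * 0
  } else {
    env <- withr::with_seed(seed, {
      x <- rnorm(n + 200)
      b <- lowpass_taps(50, 7, rate)
      y <- stats::convolve(x, rev(b), type = "filter")
      y <- y[seq_len(n)]
      y <- y - mean(y)
      pp <- max(y) - min(y)
      if (pp > 0) y / pp * profile$nonviable_amplitude else y * 0
    })
  }
  ppg_trace(env, rate, "envelope",
    meta = list(profile = profile, seed = as.integer(seed), ground_truth = TRUE)
  )
}

# slow baseline drift at the envelope rate: 3 seeded sinusoids below
# `max_freq` plus a band-limited random walk (Fourier synthesis with 1/f
# weighting, strictly zero above `max_freq`), jointly scaled to
# `amplitude` peak. The strict band limit honours the config contract:
# drift carries no content the baseline kernel's passband would keep.
drift_component <- function(n, rate, amplitude, max_freq, seed) {
  if (amplitude <= 0) return(rep(0, n))
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / rate
    d <- rep(0, n)
    f <- runif(3, 0.02, max_freq)
    ph <- runif(3, 0, 2 * pi)
    for (j in 1:3) d <- d + sin(2 * pi * f[j] * t + ph[j]) / 3
    kmax <- max(1L, floor(max_freq * n / rate))
    a <- rnorm(kmax) / seq_len(kmax)
    phw <- runif(kmax, 0, 2 * pi)
    walk <- rep(0, n)
    for (k in seq_len(kmax)) {
      walk <- walk + a[k] * cos(2 * pi * k * rate / n * t + phw[k])
    }
    walk <- walk - mean(walk)
    d <- d + walk / max(abs(walk), 1e-12) * 0.5
    d / max(abs(d), 1e-12) * amplitude
  })
}

# arrangement-dependent in-band envelope noise: broadband 0-15 Hz plus a
# well-defined 12 Hz component (the removable high-frequency signature)
arrangement_noise <- function(n, rate, arrangement, seed) {
  if (is.null(arrangement)) return(rep(0, n))
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / rate
    low <- rnorm(n + 200)
    b <- lowpass_taps(50, min(15, rate / 2 - 1), rate)
    low <- stats::convolve(low, rev(b), type = "filter")[seq_len(n)]
    low <- low - mean(low)
    low <- low / max(sd(low), 1e-12) * arrangement$lowband_noise_rms
    hb <- arrangement$highband_noise_rms
    high <- sqrt(2) * hb * sin(2 * pi * 12 * t + runif(1, 0, 2 * pi))
    low + high
  })
}

#' Modulate an envelope onto the optical carrier
#'
#' Builds the digitized raw trace
#' `X[n] = (carrier_bias + env[n]) * sin(2*pi*f_carrier/fs_raw*n + phi)`
#' plus the mains tone and white sensor noise. The envelope (upsampled by
#' zero-order hold), the slow ambient baseline drift and any
#' arrangement-dependent in-band noise all amplitude-modulate the
#' carrier, which is how they reach — and are later separated in — the
#' demodulated envelope.
#'
#' @param envelope an envelope [ppg_trace()] (the ground truth).
#' @param config a [sim_config()].
#' @param arrangement an [arrangement_preset()] or `NULL` for a clean
#'   acquisition.
#' @return A raw [ppg_trace()] at `config$fs_raw`; `meta` records every
#'   generative parameter.
#' @export
modulate <- function(envelope, config = sim_config(), arrangement = NULL) {
  if (!inherits(envelope, "ppg_trace") || trace_kind(envelope) != "envelope") {
    abort("`envelope` must be an envelope trace.")
  }
  rate <- trace_rate(envelope)
  spc <- config$fs_raw / rate
  if (abs(spc - round(spc)) > 1e-9) {
    abort("the envelope rate must divide `fs_raw` evenly.")
  }
  spc <- round(spc)
  env <- trace_values(envelope)
  n_env <- length(env)
  drift <- drift_component(
    n_env, rate, config$ambient_drift_amplitude,
    config$ambient_drift_max_freq, config$seed + 1L
  )
  arr <- arrangement_noise(n_env, rate, arrangement, config$seed + 2L)
  env_total <- env + drift + arr
  if (config$carrier_bias + min(env_total) <= 0) {
    abort("overmodulation: carrier_bias + min(envelope) must stay positive.")
  }
  n_raw <- n_env * spc
  idx <- seq_len(n_raw) - 1
  phi <- config$phase %||% withr::with_seed(config$seed, runif(1, 0, 2 * pi))
  env_up <- rep(env_total, each = spc)
  x <- (config$carrier_bias + env_up) *
    sin(2 * pi * config$f_carrier / config$fs_raw * idx + phi)
  if (config$mains_amplitude > 0) {
    x <- x + config$mains_amplitude *
      sin(2 * pi * config$mains_freq / config$fs_raw * idx +
        withr::with_seed(config$seed + 3L, runif(1, 0, 2 * pi)))
  }
  if (config$white_noise_rms > 0) {
    x <- x + withr::with_seed(
      config$seed + 4L,
      rnorm(n_raw, sd = config$white_noise_rms)
    )
  }
  ppg_trace(x, config$fs_raw, "raw",
    f_carrier = config$f_carrier,
    meta = list(
      config = unclass(config), phase = phi,
      arrangement = if (!is.null(arrangement)) arrangement$name,
      profile = trace_meta(envelope)$profile
    )
  )
}

# deterministic per-embryo sub-seeds below 2^31
derive_seeds <- function(master_seed, n) {
  if (n == 0L) return(integer(0))
  withr::with_seed(as.integer(master_seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a screening batch
#'
#' Generates a labelled batch of raw modulated traces: `n_viable`
#' pulsatile embryos and `n_nonviable` aperiodic ones, all under one
#' arrangement preset. Per-embryo sub-seeds are derived deterministically
#' from the master seed, so the same call reproduces identical traces.
#' Viable pulse rates are drawn uniformly in 3.5-4.5 Hz and amplitudes
#' within +/-15% of the arrangement's mean; non-viable residual
#' amplitudes are drawn in 0.15-0.4 mV peak-to-peak.
#'
#' @param n_viable,n_nonviable non-negative counts.
#' @param arrangement preset name or [arrangement_preset()].
#' @param config a [sim_config()].
#' @param seed master seed.
#' @return A tibble with one row per embryo: `embryo_id`, `viable`
#'   (ground-truth label), `pulse_rate`, `amplitude_mV` (generated
#'   peak-to-peak), `seed`, and list-columns `envelope` (ground truth)
#'   and `trace` (raw modulated).
#' @export
simulate_batch <- function(n_viable = 15, n_nonviable = 5, arrangement = "c",
                           config = sim_config(), seed = 1L) {
  if (n_viable < 0 || n_nonviable < 0) abort("counts must be non-negative.")
  if (is.character(arrangement)) arrangement <- arrangement_preset(arrangement)
  n <- n_viable + n_nonviable
  if (n == 0L) {
    return(tibble(
      embryo_id = character(0), viable = logical(0), pulse_rate = numeric(0),
      amplitude_mV = numeric(0), seed = integer(0),
      envelope = list(), trace = list()
    ))
  }
  seeds <- derive_seeds(seed, n)
  draws <- withr::with_seed(as.integer(seed) + 1L, list(
    rate = runif(n, 3.5, 4.5),
    amp_jitter = runif(n, 0.85, 1.15),
    nv_amp = runif(n, 0.15, 0.4)
  ))
  viable <- rep(c(TRUE, FALSE), c(n_viable, n_nonviable))
  rows <- lapply(seq_len(n), function(i) {
    prof <- embryo_profile(
      embryo_id = sprintf("embryo_%02d", i), viable = viable[i],
      pulse_rate = draws$rate[i],
      pulse_amplitude = arrangement$amplitude_scale * draws$amp_jitter[i],
      nonviable_amplitude = draws$nv_amp[i],
      seed = seeds[i]
    )
    cfg <- config
    cfg$seed <- seeds[i]
    env <- generate_envelope(prof, rate = 100, duration = config$duration)
    raw <- modulate(env, cfg, arrangement)
    tibble(
      embryo_id = prof$embryo_id, viable = prof$viable,
      pulse_rate = prof$pulse_rate,
      amplitude_mV = if (prof$viable) prof$pulse_amplitude else prof$nonviable_amplitude,
      seed = seeds[i], envelope = list(env), trace = list(raw)
    )
  })
  list_rbind(rows)
}

#' Multi-day amplitude trend
#'
#' Unimodal raised-cosine trend of pulse amplitude over incubation days:
#' maximal (1.0) at `peak_day`, strictly increasing before and strictly
#' decreasing after within `halfwidth` days, settling at `floor` beyond.
#' The floor keeps early/late signals weak but still pulsatile, matching
#' the observed day-10 low-amplitude (immature cardiovascular function)
#' and day-13/14 decline (optical attenuation by the growing embryo).
#'
#' @param day numeric vector of incubation days.
#' @param peak_day day of maximal amplitude.
#' @param halfwidth days from peak to floor (default 3).
#' @param floor minimum relative amplitude (default 0.35).
#' @return Relative amplitude in `[floor, 1]`.
#' @export
day_trend <- function(day, peak_day = 12, halfwidth = 3, floor = 0.35) {
  rc <- ifelse(
    abs(day - peak_day) < halfwidth,
    0.5 * (1 + cos(pi * (day - peak_day) / halfwidth)),
    0
  )
  floor + (1 - floor) * rc
}

#' Simulate one embryo across incubation days
#'
#' Produces one raw modulated trace per day, with the pulse amplitude
#' scaled by [day_trend()] about the profile's `peak_day`. Every day of a
#' viable embryo yields a pulsatile trace; only its amplitude changes.
#'
#' @param profile an [embryo_profile()].
#' @param days integer vector of incubation days (default 10:14).
#' @param config a [sim_config()].
#' @param arrangement preset name or [arrangement_preset()].
#' @return A tibble with columns `embryo_id`, `day`, `amplitude_mV`
#'   (ground-truth peak-to-peak that day) and list-columns `envelope`,
#'   `trace`.
#' @export
simulate_multiday <- function(profile, days = 10:14, config = sim_config(),
                              arrangement = "c") {
  if (length(days) == 0) abort("`days` must be non-empty.")
  if (is.character(arrangement)) arrangement <- arrangement_preset(arrangement)
  seeds <- derive_seeds(profile$seed, length(days))
  rows <- lapply(seq_along(days), function(i) {
    d <- days[i]
    prof_d <- profile
    prof_d$pulse_amplitude <- profile$pulse_amplitude *
      day_trend(d, profile$peak_day)
    prof_d$seed <- seeds[i]
    cfg <- config
    cfg$seed <- seeds[i]
    env <- generate_envelope(prof_d, rate = 100, duration = config$duration)
    raw <- modulate(env, cfg, arrangement)
    tibble(
      embryo_id = profile$embryo_id, day = d,
      amplitude_mV = prof_d$pulse_amplitude,
      envelope = list(env), trace = list(raw)
    )
  })
  list_rbind(rows)
}
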