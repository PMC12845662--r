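# independent brute-force oracles used across tests

# single-frequency DFT magnitude by direct summation (no fft)
direct_dft_mag <- function(x, f, rate) {
  n <- seq_along(x) - 1
  Mod(sum(x * exp(-2i * pi * f * n / rate)))
}

# full direct DFT magnitudes at the stft bin frequencies (no fft)
direct_frame_mags <- function(frame, nfft, rate) {
  vapply(
    (0:(nfft %/% 2)) * rate / nfft,
    function(f) direct_dft_mag(c(frame, numeric(nfft - length(frame))), f, rate),
    numeric(1)
  )
}

# pure-tone trace builder
tone_trace <- function(f, rate, duration, amplitude = 1, phase = 0,
                       kind = "processed") {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  ppg_trace(amplitude * sin(2 * pi * f * t + phase), rate, kind)
}

# small, fast acquisition config for pipeline tests
fast_config <- function(seed = 1L, duration = 4) {
  sim_config(duration = duration, seed = seed)
}
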