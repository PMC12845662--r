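#' Hanning window (no zero endpoints)
#'
#' `w[k] = 0.5 * (1 - cos(2*pi*k/(L+1)))`, `k = 1..L` — the symmetric
#' Hanning window without the zero endpoints, as used for the 255-point
#' STFT analysis window.
#'
#' @param length window length in samples.
#' @return Numeric vector of window values in (0, 1].
#' @export
hann_window <- function(length) {
  k <- seq_len(length)
  0.5 * (1 - cos(2 * pi * k / (length + 1)))
}

#' Short-Time Fourier Transform of a trace
#'
#' Per-frame Hanning-windowed one-sided DFT magnitudes. The 255-point
#' window is zero-padded to a 256-point DFT, giving a bin width of
#' `rate/256` (~0.39 Hz at 100 Hz). The default hop of 1 sample computes
#' the transform at every instant; larger hops trade resolution in time
#' for speed without changing per-frame magnitudes.
#'
#' @param trace a processed or envelope [ppg_trace()].
#' @param window_length analysis window length, samples (default 255).
#' @param hop frame advance, samples (default 1).
#' @param nfft DFT length (default: next power of two >= `window_length`).
#' @return A list of class `tf_map` with `magnitudes` (frames x bins,
#'   raw `|DFT|`), `times` (frame centres, s), `freqs` (Hz, spanning
#'   `[0, rate/2]`), and the window parameters.
#' @export
stft <- function(trace, window_length = 255, hop = 1, nfft = NULL) {
  if (!inherits(trace, "ppg_trace")) abort("`trace` must be a ppg_trace.")
  x <- trace_values(trace)
  if (length(x) < window_length) abort("trace shorter than the analysis window.")
  if (hop < 1) abort("`hop` must be >= 1.")
  nfft <- nfft %||% 2^ceiling(log2(window_length))
  rate <- trace_rate(trace)
  w <- hann_window(window_length)
  starts <- seq(1L, length(x) - window_length + 1L, by = hop)
  frames <- vapply(
    starts,
    function(s) c(x[s:(s + window_length - 1L)] * w, numeric(nfft - window_length)),
    numeric(nfft)
  )
  spec <- stats::mvfft(frames)
  nbin <- nfft %/% 2 + 1L
  mags <- t(Mod(spec[seq_len(nbin), , drop = FALSE]))
  structure(
    list(
      magnitudes = mags,
      times = (starts - 1 + (window_length - 1) / 2) / rate,
      freqs = (seq_len(nbin) - 1) * rate / nfft,
      window_length = window_length, hop = hop, nfft = nfft,
      window_type = "hanning", rate = rate
    ),
    class = "tf_map"
  )
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf(
    "<time-frequency map: %d frames x %d bins, 0-%g Hz, %d-point %s window, hop %d>\n",
    nrow(x$magnitudes), ncol(x$magnitudes), max(x$freqs),
    x$window_length, x$window_type, x$hop
  ))
  invisible(x)
}

#' @method as_tibble tf_map
#' @export
as_tibble.tf_map <- function(x, ...) {
  tibble(
    time_s = rep(x$times, times = length(x$freqs)),
    freq_Hz = rep(x$freqs, each = length(x$times)),
    magnitude = as.vector(x$magnitudes)
  )
}

#' @rdname tidy.viability_eval
#' @method tidy tf_map
#' @export
tidy.tf_map <- function(x, ...) as_tibble(x)

#' Spectrogram plot of a time-frequency map
#'
#' @param object a [stft()] map.
#' @param max_freq top of the displayed frequency axis, Hz.
#' @param ... unused.
#' @return A ggplot raster spectrogram.
#' @method autoplot tf_map
#' @export
autoplot.tf_map <- function(object, max_freq = 15, ...) {
  df <- as_tibble(object)
  df <- df[df$freq_Hz <= max_freq, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_Hz,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|STFT|") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}

#' Dominant frequency of a time-frequency map
#'
#' Frequency of the maximal time-averaged STFT magnitude within a band.
#' Ties break toward the lower frequency.
#'
#' @param map a [stft()] map.
#' @param band two-element numeric, Hz (default `c(1, 15)` — above
#'   residual drift, below the noise floor of interest).
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(map, band = c(1, 15)) {
  if (length(band) != 2 || band[1] >= band[2]) abort("`band` must be an increasing interval.")
  sel <- which(map$freqs >= band[1] & map$freqs <= band[2])
  if (length(sel) == 0) abort("`band` contains no frequency bins.")
  avg <- colMeans(map$magnitudes[, sel, drop = FALSE])
  map$freqs[sel[which.max(avg)]]
}

#' Spectral energy concentration about a centre frequency
#'
#' Ratio of time-averaged STFT energy within `center +/- halfwidth` to
#' the total in the 0.5-15 Hz analysis band (bins below 0.5 Hz are
#' excluded everywhere so residual drift cannot dominate). A pulsatile
#' signal concentrates its energy near the pulse rate (ratio near 1); an
#' aperiodic one spreads it (the "diffuse" signature), giving a small
#' ratio.
#'
#' @param map a [stft()] map.
#' @param center centre frequency, Hz.
#' @param halfwidth half-width of the concentration band, Hz (default 1).
#' @return Ratio in `[0, 1]`; 0 (with a warning) for an all-zero map.
#' @export
spectral_concentration <- function(map, center, halfwidth = 1) {
  if (halfwidth <= 0) abort("`halfwidth` must be positive.")
  if (center - halfwidth < 0 || center + halfwidth > max(map$freqs)) {
    abort("concentration band extends beyond the map's frequency range.")
  }
  energy <- colMeans(map$magnitudes^2)
  denom_sel <- map$freqs >= 0.5 & map$freqs <= 15
  num_sel <- denom_sel & map$freqs >= center - halfwidth & map$freqs <= center + halfwidth
  denom <- sum(energy[denom_sel])
  if (denom <= 0) {
    warn("trace has no energy in the 0.5-15 Hz band; concentration set to 0.")
    return(0)
  }
  sum(energy[num_sel]) / denom
}
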