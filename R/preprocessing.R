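#' Zero-mean triangular kernel
#'
#' Builds the baseline-suppression kernel: a symmetric triangular
#' (Bartlett-shaped, non-zero endpoints) sequence whose mean is
#' subtracted and which is then normalized to unit peak absolute value.
#' Its coefficients sum to zero by construction, so correlating a signal
#' with it annihilates any constant (DC) component and strongly
#' attenuates slow baseline drift while passing the pulsatile band.
#'
#' @param length kernel length in samples (default 10, chosen at the
#'   100 Hz envelope rate); minimum effective length 3 — a length-2
#'   "triangle" degenerates to the zero vector after mean removal and is
#'   rejected.
#' @return Numeric vector of `length` coefficients summing to zero.
#' @export
zero_mean_triangular_kernel <- function(length = 10) {
  if (length < 3) abort("`length` must be at least 3 (degenerate triangle).")
  k <- seq_len(length)
  w <- 1 - abs(2 * k - length - 1) / length
  w <- w - mean(w)
  w <- w / max(abs(w))
  w - sum(w) / length # force the zero sum through the normalization
}

# internal: unity-DC-gain windowed-sinc low-pass taps
lowpass_taps <- function(order, cutoff, rate) {
  b <- signal::fir1(order, cutoff / (rate / 2), type = "low")
  b / sum(b)
}

# sliding dot product with symmetric (mirror) edge padding, same-length output
sliding_correlate <- function(x, k) {
  L <- length(k)
  left <- (L - 1) %/% 2
  right <- L - 1 - left
  n <- length(x)
  pad <- c(
    if (left > 0) x[left:1] else numeric(0),
    x,
    if (right > 0) x[n:(n - right + 1)] else numeric(0)
  )
  # k is symmetric in every use here, so correlation equals convolution
  stats::convolve(pad, rev(k), type = "filter")
}

#' Suppress baseline drift by correlation with a zero-mean kernel
#'
#' Slides the [zero_mean_triangular_kernel()] along the envelope as a dot
#' product (same-length output via symmetric edge padding). The zero-sum
#' kernel maps any constant input to zero exactly and acts as a gentle
#' high-pass, removing the demodulated DC term and slow drift while
#' keeping the ~4 Hz pulse. The operation is linear in the input.
#'
#' @param envelope an envelope or processed [ppg_trace()].
#' @param kernel_length kernel length in samples (default 10).
#' @return A processed [ppg_trace()]; `ceiling(kernel_length/2)` samples
#'   at each edge are added to the transient count.
#' @export
remove_baseline <- function(envelope, kernel_length = 10) {
  if (!inherits(envelope, "ppg_trace")) abort("`envelope` must be a ppg_trace.")
  x <- trace_values(envelope)
  if (length(x) <= kernel_length) abort("input shorter than the kernel.")
  k <- zero_mean_triangular_kernel(kernel_length)
  y <- sliding_correlate(x, k)
  ppg_trace(y, trace_rate(envelope), "processed",
    meta = trace_meta(envelope),
    log = append_log(
      processing_log(envelope), "remove_baseline",
      kernel_length = kernel_length, rate = trace_rate(envelope)
    ),
    transient = trace_transient(envelope) + ceiling(kernel_length / 2)
  )
}

#' Design the linear-phase low-pass FIR filter
#'
#' Windowed-sinc design (Hamming window by default, the conventional
#' default of `fir1`-style designers): `order + 1` symmetric taps,
#' rescaled to exactly unity DC gain. Tap symmetry guarantees linear
#' phase — every passband component is delayed by exactly `order/2`
#' samples, so the pulse waveform shape is preserved.
#'
#' @param order filter order (even; default 100).
#' @param cutoff -6 dB cutoff frequency, Hz (default 7 — just above the
#'   embryonic pulse band).
#' @param rate sampling rate of the signal the filter will be applied
#'   to, Hz (default 100).
#' @param design_window `"hamming"` or `"hanning"`.
#' @return A list of class `filter_spec` with `order`, `cutoff`, `rate`,
#'   `design_window` and `taps`.
#' @export
design_lowpass <- function(order = 100, cutoff = 7, rate = 100,
                           design_window = c("hamming", "hanning")) {
  design_window <- match.arg(design_window)
  if (order %% 2 != 0 || order < 2) abort("`order` must be a positive even integer.")
  if (cutoff <= 0 || cutoff >= rate / 2) abort("`cutoff` must lie in (0, rate/2).")
  win <- switch(design_window,
    hamming = signal::hamming(order + 1),
    hanning = hann_window(order + 1)
  )
  b <- signal::fir1(order, cutoff / (rate / 2), type = "low", window = win)
  b <- (b + rev(b)) / 2 # enforce exact tap symmetry (linear phase)
  b <- b / sum(b)
  structure(
    list(
      order = order, cutoff = cutoff, rate = rate,
      design_window = design_window, taps = as.numeric(b)
    ),
    class = "filter_spec"
  )
}

#' Apply the low-pass filter with group-delay compensation
#'
#' Convolves the trace with the filter taps; the output is realigned by
#' the `order/2`-sample group delay (symmetric edge padding, same-length
#' output), so filtered and unfiltered traces stay time-aligned.
#'
#' @param trace a processed or envelope [ppg_trace()].
#' @param spec a [design_lowpass()] filter.
#' @return A processed [ppg_trace()]; `order/2` samples at each edge are
#'   added to the transient count.
#' @export
apply_lowpass <- function(trace, spec = design_lowpass(rate = trace_rate(trace))) {
  if (!inherits(trace, "ppg_trace")) abort("`trace` must be a ppg_trace.")
  if (!inherits(spec, "filter_spec")) abort("`spec` must be a filter_spec.")
  x <- trace_values(trace)
  if (length(x) <= spec$order) abort("trace shorter than the filter order.")
  if (abs(spec$rate - trace_rate(trace)) > 1e-9) {
    abort("filter was designed for a different sampling rate.")
  }
  y <- sliding_correlate(x, spec$taps)
  ppg_trace(y, trace_rate(trace), "processed",
    meta = trace_meta(trace),
    log = append_log(
      processing_log(trace), "lowpass",
      order = spec$order, cutoff = spec$cutoff,
      design_window = spec$design_window, rate = spec$rate
    ),
    transient = trace_transient(trace) + spec$order %/% 2
  )
}

#' Frequency response magnitude of a tap sequence
#'
#' @param taps filter/kernel coefficients.
#' @param freq frequencies at which to evaluate, Hz.
#' @param rate sampling rate, Hz.
#' @return `|H(f)|`, the magnitude response.
#' @export
tap_response <- function(taps, freq, rate) {
  vapply(freq, function(f) {
    j <- seq_along(taps) - 1
    Mod(sum(taps * exp(-2i * pi * f * j / rate)))
  }, numeric(1))
}

#' Gain of the preprocessing cascade at a frequency
#'
#' The unit-peak normalization of the baseline kernel means the cascade
#' gain at the pulse frequency is not unity; amplitude features taken
#' after preprocessing are therefore divided by this gain (evaluated at
#' the measured dominant frequency) to report physical mV.
#'
#' Stages are read from a trace's processing log when given, so the gain
#' always reflects the kernels actually applied.
#'
#' @param freq frequency, Hz.
#' @param rate sampling rate, Hz.
#' @param kernel_length baseline-kernel length (`NULL` if that stage was
#'   not applied).
#' @param lp_order,lp_cutoff,lp_window low-pass parameters (`lp_order =
#'   NULL` if not applied).
#' @return Scalar gain `|H_kernel(f)| * |H_lowpass(f)|`.
#' @export
cascade_gain <- function(freq, rate = 100, kernel_length = 10,
                         lp_order = 100, lp_cutoff = 7,
                         lp_window = "hamming") {
  g <- 1
  if (!is.null(kernel_length)) {
    g <- g * tap_response(zero_mean_triangular_kernel(kernel_length), freq, rate)
  }
  if (!is.null(lp_order)) {
    spec <- design_lowpass(lp_order, lp_cutoff, rate, lp_window)
    g <- g * tap_response(spec$taps, freq, rate)
  }
  g
}

# cascade gain reconstructed from a processing log
gain_from_log <- function(log, freq, rate) {
  g <- rep(1, length(freq))
  for (e in log) {
    if (e$stage == "remove_baseline") {
      g <- g * tap_response(zero_mean_triangular_kernel(e$kernel_length), freq, rate)
    } else if (e$stage == "lowpass") {
      spec <- design_lowpass(e$order, e$cutoff, rate, e$design_window)
      g <- g * tap_response(spec$taps, freq, rate)
    }
  }
  g
}

#' Run the full cleaning chain on an envelope
#'
#' Baseline suppression by the zero-mean triangular kernel, then the
#' linear-phase low-pass — in that order, mirroring the acquisition
#' pipeline.
#'
#' @param envelope an envelope [ppg_trace()].
#' @param kernel_length baseline kernel length (default 10).
#' @param lp_order,lp_cutoff low-pass order and cutoff (defaults 100, 7 Hz).
#' @return A processed [ppg_trace()] with both stages logged.
#' @export
preprocess <- function(envelope, kernel_length = 10, lp_order = 100, lp_cutoff = 7) {
  x <- remove_baseline(envelope, kernel_length)
  apply_lowpass(x, design_lowpass(lp_order, lp_cutoff, trace_rate(x)))
}
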