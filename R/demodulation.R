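#' Orthogonal lock-in reference pair
#'
#' Precomputes the sine and cosine references `S[n] = sin(2*pi*f/fs*n)`,
#' `C[n] = cos(2*pi*f/fs*n)` used by phase-sensitive detection. The
#' window is restricted to whole carrier cycles so that the references
#' are exactly orthogonal and the amplitude scaling is exact:
#' `sum(S^2) = sum(C^2) = N/2` and `sum(S*C) = 0` over full periods.
#'
#' @param f_carrier carrier frequency, Hz.
#' @param fs_raw raw sampling rate, Hz; `fs_raw / f_carrier` must be an
#'   integer (48 at the 96 kHz / 2 kHz defaults).
#' @param n_cycles number of carrier cycles per demodulation window
#'   (default 20, i.e. N = 960 samples and a 100 Hz envelope rate).
#' @return A list of class `reference_pair` with `sine`, `cosine`,
#'   `length`, `f_ref`, `fs_raw`.
#' @export
make_references <- function(f_carrier = 2000, fs_raw = 96000, n_cycles = 20) {
  spc <- fs_raw / f_carrier
  if (abs(spc - round(spc)) > 1e-9) {
    abort("`fs_raw / f_carrier` must be an integer number of samples per cycle.")
  }
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  n <- round(spc) * n_cycles
  idx <- seq_len(n) - 1
  w <- 2 * pi * f_carrier / fs_raw * idx
  structure(
    list(
      sine = sin(w), cosine = cos(w), length = n,
      f_ref = f_carrier, fs_raw = fs_raw, n_cycles = n_cycles
    ),
    class = "reference_pair"
  )
}

#' Demodulate one window by phase-sensitive detection
#'
#' Correlates a raw window against the sine and cosine references:
#' `I = sum(X * S)`, `Q = sum(X * C)`, and combines them as
#' `amplitude = (2/N) * sqrt(I^2 + Q^2)`, so a pure in-band tone of
#' amplitude A is returned as A regardless of its phase. The
#' accumulation acts as a narrowband filter about the carrier, rejecting
#' mains and ambient-light tones.
#'
#' @param window numeric vector (mV) of length `refs$length`.
#' @param refs a [make_references()] pair.
#' @return A list with `I`, `Q`, and `amplitude` (mV).
#' @export
demodulate_window <- function(window, refs) {
  if (length(window) != refs$length) {
    abort("`window` length must equal the reference length.")
  }
  I <- sum(window * refs$sine)
  Q <- sum(window * refs$cosine)
  list(I = I, Q = Q, amplitude = 2 / refs$length * sqrt(I^2 + Q^2))
}

#' Demodulate a raw trace to its PPG envelope
#'
#' Applies [demodulate_window()] over consecutive non-overlapping windows
#' of `refs$length` samples, producing the envelope at rate
#' `fs_raw / N` (100 Hz at the defaults). A trailing partial window is
#' discarded. The demodulated DC term (the static-attenuation
#' `carrier_bias`) is retained here; the baseline-suppression stage
#' removes it downstream.
#'
#' @param trace a raw [ppg_trace()].
#' @param refs a [make_references()] pair, or `NULL` to build one from
#'   the trace's carrier metadata with `n_cycles` cycles.
#' @param n_cycles window length in carrier cycles when `refs` is `NULL`.
#' @return An envelope [ppg_trace()]; `meta` records the window length,
#'   carrier and scaling, and the processing log gains a `demodulate`
#'   entry.
#' @export
demodulate <- function(trace, refs = NULL, n_cycles = 20) {
  if (!inherits(trace, "ppg_trace") || trace_kind(trace) != "raw") {
    abort("`trace` must be a raw trace.")
  }
  fs <- trace_rate(trace)
  fc <- attr(trace, "f_carrier")
  if (is.null(refs)) refs <- make_references(fc, fs, n_cycles)
  if (refs$fs_raw != fs || refs$f_ref != fc) {
    abort("reference pair does not match the trace's sampling/carrier rates.")
  }
  x <- trace_values(trace)
  n <- refs$length
  m <- length(x) %/% n
  if (m < 1) abort("trace shorter than one demodulation window.")
  xm <- matrix(x[seq_len(m * n)], nrow = n)
  I <- colSums(xm * refs$sine)
  Q <- colSums(xm * refs$cosine)
  amp <- 2 / n * sqrt(I^2 + Q^2)
  ppg_trace(amp, fs / n, "envelope",
    meta = c(trace_meta(trace), list(window_N = n, f_carrier = fc, scaling = "2/N")),
    log = append_log(
      processing_log(trace), "demodulate",
      N = n, f_carrier = fc, scaling = "2/N", rate = fs / n
    )
  )
}
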