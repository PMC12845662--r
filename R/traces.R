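#' PPG trace containers
#'
#' All signals in the package travel as *traces*: tibbles with a `time_s`
#' column and a `value_mV` column, carrying their sampling rate and
#' provenance as attributes. Three kinds exist:
#'
#' * `"raw"` — the digitized carrier-modulated photodetector signal
#'   (typically 96 kHz with a 2 kHz carrier);
#' * `"envelope"` — the demodulated PPG amplitude sequence (typically
#'   100 Hz), always non-negative;
#' * `"processed"` — an envelope after baseline suppression and/or
#'   low-pass filtering, with a `processing_log` recording each stage.
#'
#' @param values numeric vector of samples, in mV.
#' @param rate sampling rate in Hz.
#' @param kind one of `"raw"`, `"envelope"`, `"processed"`.
#' @param f_carrier carrier frequency in Hz (raw traces only).
#' @param meta named list of free-form provenance.
#' @param log list of processing-log entries (`stage`, parameters).
#' @param transient integer, number of edge samples on each side that are
#'   filter transients and must be excluded from feature windows.
#'
#' @return A tibble of class `ppg_trace` with columns `time_s`, `value_mV`.
#' @export
ppg_trace <- function(values, rate, kind = c("envelope", "raw", "processed"),
                      f_carrier = NULL, meta = list(), log = list(),
                      transient = 0L) {
  kind <- match.arg(kind)
  if (!is.numeric(values) || length(values) < 1L) {
    abort("`values` must be a non-empty numeric vector.")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).")
  }
  if (kind == "raw") {
    if (is.null(f_carrier)) abort("raw traces need `f_carrier`.")
    if (rate <= 2 * f_carrier) {
      abort("`rate` must exceed twice the carrier frequency.")
    }
  }
  out <- tibble(
    time_s = (seq_along(values) - 1) / rate,
    value_mV = as.numeric(values)
  )
  class(out) <- c(paste0("ppg_", kind), "ppg_trace", class(out))
  attr(out, "rate") <- rate
  attr(out, "kind") <- kind
  attr(out, "f_carrier") <- f_carrier
  attr(out, "meta") <- meta
  attr(out, "processing_log") <- log
  attr(out, "transient") <- as.integer(transient)
  out
}

#' Trace accessors
#'
#' @param x a [ppg_trace()].
#' @return `trace_values()` the sample vector; `trace_rate()` the rate in
#'   Hz; `trace_kind()` the trace kind; `trace_meta()` the provenance
#'   list; `processing_log()` the ordered list of applied stages;
#'   `trace_transient()` the per-edge transient sample count;
#'   `steady_values()` the samples with both transient edges removed.
#' @export
trace_values <- function(x) x$value_mV

#' @rdname trace_values
#' @export
trace_rate <- function(x) attr(x, "rate")

#' @rdname trace_values
#' @export
trace_kind <- function(x) attr(x, "kind")

#' @rdname trace_values
#' @export
trace_meta <- function(x) attr(x, "meta")

#' @rdname trace_values
#' @export
processing_log <- function(x) attr(x, "processing_log")

#' @rdname trace_values
#' @export
trace_transient <- function(x) attr(x, "transient") %||% 0L

#' @rdname trace_values
#' @export
steady_values <- function(x) {
  v <- trace_values(x)
  tr <- trace_transient(x)
  if (2L * tr >= length(v)) abort("trace is all transient; nothing steady to analyse.")
  if (tr > 0L) v[(tr + 1L):(length(v) - tr)] else v
}

append_log <- function(log, stage, ...) {
  c(log, list(c(list(stage = stage), list(...))))
}

#' @export
print.ppg_trace <- function(x, ...) {
  cat(sprintf(
    "<%s trace: %d samples @ %g Hz%s>\n",
    trace_kind(x), nrow(x), trace_rate(x),
    if (!is.null(attr(x, "f_carrier"))) {
      sprintf(", carrier %g Hz", attr(x, "f_carrier"))
    } else ""
  ))
  stages <- vapply(processing_log(x), function(e) e$stage, character(1))
  if (length(stages)) cat(" stages:", paste(stages, collapse = " -> "), "\n")
  NextMethod()
}

#' Plot a PPG trace
#'
#' @param object a [ppg_trace()].
#' @param ... unused.
#' @return A ggplot of amplitude (mV) against time (s).
#' @method autoplot ppg_trace
#' @export
autoplot.ppg_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (mV)",
      title = sprintf("%s trace @ %g Hz", trace_kind(object), trace_rate(object))
    )
}

#' @importFrom rlang .data
NULL
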