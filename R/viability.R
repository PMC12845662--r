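#' Decision thresholds for the viability rule
#'
#' The classifier is a conjunction of four criteria distilled from the
#' observed viable / non-viable feature gap: processed viable amplitudes
#' exceed 1 mV while non-viable residuals stay at or below 0.4 mV, and
#' viable spectra show a concentrated peak near 4 Hz with clear
#' periodicity. `amplitude_min` therefore sits strictly inside the
#' (0.4, 1.0) mV gap.
#'
#' @param amplitude_min minimum gain-compensated peak-to-peak amplitude,
#'   mV (default 0.7, the midpoint of the reported gap).
#' @param freq_band admissible dominant-frequency band, Hz (default
#'   `c(2, 6)` about the ~4 Hz embryonic pulse).
#' @param concentration_min minimum spectral concentration (default 0.5).
#' @param periodicity_min minimum autocorrelation periodicity (default 0.3).
#' @return A list of class `viability_thresholds`.
#' @export
viability_thresholds <- function(amplitude_min = 0.7, freq_band = c(2, 6),
                                 concentration_min = 0.5, periodicity_min = 0.3) {
  if (amplitude_min <= 0.4 || amplitude_min >= 1.0) {
    abort("`amplitude_min` must lie strictly between 0.4 and 1.0 mV.")
  }
  if (length(freq_band) != 2 || freq_band[1] >= freq_band[2]) {
    abort("`freq_band` must be an increasing interval.")
  }
  structure(
    list(
      amplitude_min = amplitude_min, freq_band = freq_band,
      concentration_min = concentration_min, periodicity_min = periodicity_min
    ),
    class = "viability_thresholds"
  )
}

#' Extract viability features from a processed trace
#'
#' Computes, over the steady region (transient filter edges excluded):
#'
#' * `peak_freq_Hz` — dominant time-averaged STFT frequency in 1-15 Hz;
#' * `peak_to_peak_mV` — max minus min, divided by the preprocessing
#'   cascade's gain at `peak_freq_Hz` (reconstructed from the processing
#'   log) so the value is in physical mV;
#' * `concentration` — spectral energy concentration in
#'   `peak_freq_Hz +/- 1` Hz;
#' * `periodicity` — maximum of the biased normalized autocorrelation
#'   over lags corresponding to pulse rates 2-6 Hz.
#'
#' @param trace a processed [ppg_trace()].
#' @param map optional precomputed [stft()] of the steady region;
#'   computed if `NULL`.
#' @param band search band for the dominant frequency, Hz.
#' @param stft_window,stft_hop STFT parameters used when `map` is `NULL`.
#' @return A one-row tibble of class `viability_features`.
#' @export
extract_features <- function(trace, map = NULL, band = c(1, 15),
                             stft_window = 255, stft_hop = 1) {
  if (!inherits(trace, "ppg_trace")) abort("`trace` must be a ppg_trace.")
  rate <- trace_rate(trace)
  steady <- steady_values(trace)
  steady_trace <- ppg_trace(steady, rate, "processed",
    meta = trace_meta(trace), log = processing_log(trace)
  )
  if (is.null(map)) map <- stft(steady_trace, stft_window, stft_hop)
  peak_freq <- dominant_frequency(map, band)
  gain <- gain_from_log(processing_log(trace), peak_freq, rate)
  pp <- (max(steady) - min(steady)) / max(gain, 1e-12)
  conc <- spectral_concentration(map, peak_freq, 1)
  x <- steady - mean(steady)
  denom <- sum(x^2)
  lags <- seq(ceiling(rate / 6), floor(rate / 2))
  per <- if (denom <= 0) 0 else {
    max(vapply(lags, function(l) {
      n <- length(x)
      sum(x[seq_len(n - l)] * x[(l + 1):n]) / denom
    }, numeric(1)))
  }
  out <- tibble(
    peak_freq_Hz = peak_freq, peak_to_peak_mV = pp,
    concentration = conc, periodicity = min(max(per, 0), 1)
  )
  class(out) <- c("viability_features", class(out))
  out
}

#' Classify an embryo as viable or non-viable
#'
#' Applies the four-criterion conjunction: viable iff the
#' gain-compensated peak-to-peak amplitude exceeds `amplitude_min`, the
#' dominant frequency lies in `freq_band`, the spectral concentration is
#' at least `concentration_min`, and the periodicity at least
#' `periodicity_min`. Per-criterion evidence is returned alongside the
#' label.
#'
#' @param features a [extract_features()] row (or any data frame with the
#'   four feature columns).
#' @param thresholds a [viability_thresholds()].
#' @return A one-row tibble of class `viability_call`: `label` (factor
#'   viable/nonviable), the four evidence logicals, and the features.
#' @export
classify_viability <- function(features, thresholds = viability_thresholds()) {
  stopifnot(all(c(
    "peak_freq_Hz", "peak_to_peak_mV", "concentration", "periodicity"
  ) %in% names(features)))
  if (!all(is.finite(unlist(features[1, c(
    "peak_freq_Hz", "peak_to_peak_mV", "concentration", "periodicity"
  )])))) {
    abort("features must be finite.")
  }
  ev <- tibble(
    amplitude_ok = features$peak_to_peak_mV > thresholds$amplitude_min,
    frequency_ok = features$peak_freq_Hz >= thresholds$freq_band[1] &
      features$peak_freq_Hz <= thresholds$freq_band[2],
    concentration_ok = features$concentration >= thresholds$concentration_min,
    periodicity_ok = features$periodicity >= thresholds$periodicity_min
  )
  out <- dplyr::bind_cols(
    tibble(label = factor(
      ifelse(ev$amplitude_ok & ev$frequency_ok & ev$concentration_ok & ev$periodicity_ok,
        "viable", "nonviable"
      ),
      levels = c("viable", "nonviable")
    )),
    ev, as_tibble(features)
  )
  class(out) <- c("viability_call", class(out))
  out
}

#' Evaluate classifier calls against ground-truth labels
#'
#' @param calls data frame with `embryo_id` and `label` (from
#'   [classify_viability()] rows bound together).
#' @param truth data frame with `embryo_id` and logical `viable`.
#' @return A list of class `viability_eval`: confusion counts (viable =
#'   positive class), `accuracy` (%), `sensitivity`, `specificity`, `n`.
#'   [tidy()] gives the per-embryo comparison, [glance()] the one-row
#'   summary.
#' @export
evaluate_batch <- function(calls, truth) {
  if (nrow(calls) == 0) abort("`calls` is empty.")
  if (!setequal(calls$embryo_id, truth$embryo_id) ||
    nrow(calls) != nrow(truth)) {
    abort("`calls` and `truth` must cover the same embryo ids.")
  }
  merged <- left_join(
    as_tibble(calls[, c("embryo_id", "label")]),
    as_tibble(truth[, c("embryo_id", "viable")]),
    by = "embryo_id"
  )
  pred_viable <- merged$label == "viable"
  tp <- sum(pred_viable & merged$viable)
  tn <- sum(!pred_viable & !merged$viable)
  fp <- sum(pred_viable & !merged$viable)
  fn <- sum(!pred_viable & merged$viable)
  structure(
    list(
      comparison = mutate(merged, correct = pred_viable == .data$viable),
      tp = tp, tn = tn, fp = fp, fn = fn, n = nrow(merged),
      accuracy = 100 * (tp + tn) / nrow(merged),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ),
    class = "viability_eval"
  )
}

#' Tidiers for evaluation and capture results
#'
#' @param x a `viability_eval`, `capture_assessment` or `tf_map` object.
#' @param ... unused.
#' @return A tibble: per-embryo rows for [tidy()], a one-row summary for
#'   [glance()].
#' @method tidy viability_eval
#' @export
tidy.viability_eval <- function(x, ...) x$comparison

#' @rdname tidy.viability_eval
#' @method glance viability_eval
#' @export
glance.viability_eval <- function(x, ...) {
  tibble(
    n = x$n, tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
    accuracy = x$accuracy, sensitivity = x$sensitivity,
    specificity = x$specificity
  )
}

#' @export
print.viability_eval <- function(x, ...) {
  cat(sprintf(
    "<viability evaluation: n=%d, accuracy %.1f%% (TP %d, TN %d, FP %d, FN %d)>\n",
    x$n, x$accuracy, x$tp, x$tn, x$fp, x$fn
  ))
  invisible(x)
}

#' Assess multi-day PPG capture
#'
#' A day's acquisition counts as *captured* when the processed trace is
#' pulsatile: periodicity at or above `periodicity_min` and dominant
#' frequency inside `freq_band`. The amplitude criterion is deliberately
#' excluded — day-10 signals are weak but still pulsatile. Missing
#' embryo-day cells (relative to the full embryo x day grid) are
#' recorded as not captured, with a warning.
#'
#' @param results data frame with `embryo_id`, `day`, `periodicity` and
#'   `peak_freq_Hz` columns (e.g. from [monitor_batch()]).
#' @param thresholds a [viability_thresholds()].
#' @param embryos,days expected grid; defaults to the ids/days present.
#' @return A list of class `capture_assessment`: `matrix` (tibble
#'   embryo_id x day with `captured`), `success_rate` (%), `n_cells`.
#' @export
assess_capture <- function(results, thresholds = viability_thresholds(),
                           embryos = unique(results$embryo_id),
                           days = sort(unique(results$day))) {
  grid <- tidyr::expand_grid(embryo_id = embryos, day = days)
  scored <- mutate(
    as_tibble(results),
    captured = .data$periodicity >= thresholds$periodicity_min &
      .data$peak_freq_Hz >= thresholds$freq_band[1] &
      .data$peak_freq_Hz <= thresholds$freq_band[2]
  )
  full <- left_join(grid, scored, by = c("embryo_id", "day"))
  if (anyNA(full$captured)) {
    warn(sprintf(
      "%d embryo-day cell(s) missing; recorded as not captured.",
      sum(is.na(full$captured))
    ))
    full$captured[is.na(full$captured)] <- FALSE
  }
  structure(
    list(
      matrix = full[, c("embryo_id", "day", "captured")],
      detail = full,
      success_rate = 100 * mean(full$captured),
      n_cells = nrow(full)
    ),
    class = "capture_assessment"
  )
}

#' @rdname tidy.viability_eval
#' @method tidy capture_assessment
#' @export
tidy.capture_assessment <- function(x, ...) x$matrix

#' @rdname tidy.viability_eval
#' @method glance capture_assessment
#' @export
glance.capture_assessment <- function(x, ...) {
  tibble(
    n_cells = x$n_cells, n_captured = sum(x$matrix$captured),
    success_rate = x$success_rate
  )
}

#' @export
print.capture_assessment <- function(x, ...) {
  cat(sprintf(
    "<capture assessment: %d/%d embryo-days captured (%.1f%%)>\n",
    sum(x$matrix$captured), x$n_cells, x$success_rate
  ))
  invisible(x)
}
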