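#' Run the full analysis chain on one raw trace
#'
#' Lock-in demodulation, baseline suppression, low-pass filtering, STFT
#' feature extraction and the viability call — the complete path from a
#' digitized modulated trace to a label.
#'
#' @param raw a raw [ppg_trace()].
#' @param n_cycles demodulation window, carrier cycles (default 20).
#' @param kernel_length baseline kernel length (default 10).
#' @param lp_order,lp_cutoff low-pass parameters (defaults 100, 7 Hz).
#' @param stft_window,stft_hop STFT parameters (defaults 255, 1).
#' @param thresholds a [viability_thresholds()].
#' @param keep_intermediates if `TRUE`, attach `processed` and `map`
#'   list-columns.
#' @return A one-row tibble: `embryo_id` (from the trace's provenance,
#'   `NA` if absent), the viability call and features.
#' @export
process_trace <- function(raw, n_cycles = 20, kernel_length = 10,
                          lp_order = 100, lp_cutoff = 7,
                          stft_window = 255, stft_hop = 1,
                          thresholds = viability_thresholds(),
                          keep_intermediates = FALSE) {
  env <- if (trace_kind(raw) == "raw") demodulate(raw, n_cycles = n_cycles) else raw
  proc <- preprocess(env, kernel_length, lp_order, lp_cutoff)
  steady <- ppg_trace(steady_values(proc), trace_rate(proc), "processed",
    meta = trace_meta(proc), log = processing_log(proc)
  )
  map <- stft(steady, stft_window, stft_hop)
  feats <- extract_features(proc, map = map, stft_window = stft_window,
                            stft_hop = stft_hop)
  call <- classify_viability(feats, thresholds)
  prof <- trace_meta(raw)$profile
  out <- dplyr::bind_cols(
    tibble(embryo_id = if (!is.null(prof)) prof$embryo_id else NA_character_),
    call
  )
  if (keep_intermediates) {
    out$processed <- list(proc)
    out$map <- list(map)
  }
  out
}

#' Screen a simulated (or loaded) batch
#'
#' Runs [process_trace()] on every trace of a batch tibble and, when a
#' ground-truth `viable` column is present, evaluates the calls against
#' it.
#'
#' @param batch tibble with `embryo_id`, a `trace` list-column of raw
#'   traces, and optionally a logical `viable` truth column (as produced
#'   by [simulate_batch()]).
#' @param thresholds a [viability_thresholds()].
#' @param ... passed to [process_trace()].
#' @return A tibble of per-embryo calls of class `screen_result`; when
#'   truth was present its `evaluation` attribute holds the
#'   [evaluate_batch()] result (also available via [glance()]).
#' @export
screen_batch <- function(batch, thresholds = viability_thresholds(), ...) {
  if (nrow(batch) == 0) {
    return(structure(tibble(), class = c("screen_result", class(tibble()))))
  }
  calls <- list_rbind(lapply(seq_len(nrow(batch)), function(i) {
    row <- process_trace(batch$trace[[i]], thresholds = thresholds, ...)
    row$embryo_id <- batch$embryo_id[i]
    row
  }))
  if ("viable" %in% names(batch)) {
    calls$viable <- batch$viable
    attr(calls, "evaluation") <-
      evaluate_batch(calls, batch[, c("embryo_id", "viable")])
  }
  class(calls) <- c("screen_result", class(calls))
  calls
}

#' @rdname tidy.viability_eval
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  ev <- attr(x, "evaluation")
  if (is.null(ev)) abort("no ground-truth labels; nothing to glance at.")
  glance(ev)
}

#' Process a multi-day monitoring batch
#'
#' Runs the full chain on every embryo-day trace of a multi-day tibble
#' (rows as produced by [simulate_multiday()], possibly bound over
#' several embryos) and assesses capture.
#'
#' @param multiday tibble with `embryo_id`, `day` and a `trace`
#'   list-column.
#' @param thresholds a [viability_thresholds()].
#' @param ... passed to [process_trace()].
#' @return A list of class `monitor_result`: `results` (per embryo-day
#'   features and calls, including the measured `peak_to_peak_mV`) and
#'   `capture` (the [assess_capture()] object).
#' @export
monitor_batch <- function(multiday, thresholds = viability_thresholds(), ...) {
  if (nrow(multiday) == 0) abort("`multiday` is empty.")
  res <- list_rbind(lapply(seq_len(nrow(multiday)), function(i) {
    row <- process_trace(multiday$trace[[i]], thresholds = thresholds, ...)
    row$embryo_id <- multiday$embryo_id[i]
    row$day <- multiday$day[i]
    row
  }))
  structure(
    list(results = res, capture = assess_capture(res, thresholds)),
    class = "monitor_result"
  )
}

#' @rdname tidy.viability_eval
#' @method tidy monitor_result
#' @export
tidy.monitor_result <- function(x, ...) x$results

#' @rdname tidy.viability_eval
#' @method glance monitor_result
#' @export
glance.monitor_result <- function(x, ...) glance(x$capture)

#' @export
print.monitor_result <- function(x, ...) {
  print(x$capture)
  invisible(x)
}

#' Per-embryo day of maximal measured amplitude
#'
#' @param x a [monitor_batch()] result.
#' @return Tibble `embryo_id`, `peak_day_measured`.
#' @export
measured_peak_day <- function(x) {
  res <- x$results
  res |>
    group_by(.data$embryo_id) |>
    summarise(
      peak_day_measured = .data$day[which.max(.data$peak_to_peak_mV)],
      .groups = "drop"
    )
}
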