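#' Read and write traces as CSV
#'
#' Two-column CSV (`time_s`, `value_mV`). The sampling rate is
#' reconstructed from the time column on read; the trace kind and
#' carrier frequency travel in an optional JSON sidecar written next to
#' the CSV (`<file>.meta.json`).
#'
#' @param trace a [ppg_trace()].
#' @param path output file path.
#' @param sidecar write/read the JSON metadata sidecar.
#' @return `write_trace_csv()` the path, invisibly; `read_trace_csv()` a
#'   [ppg_trace()].
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  readr::write_csv(as_tibble(trace)[, c("time_s", "value_mV")], path)
  if (sidecar) {
    meta <- list(
      kind = trace_kind(trace), rate = trace_rate(trace),
      f_carrier = attr(trace, "f_carrier"),
      transient = trace_transient(trace),
      processing_log = processing_log(trace)
    )
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
      auto_unbox = TRUE, null = "null", digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, sidecar = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "value_mV") %in% names(df))) {
    abort("trace CSV must have columns time_s, value_mV.")
  }
  if (nrow(df) < 2) abort("trace CSV must hold at least 2 samples.")
  rate <- 1 / stats::median(diff(df$time_s))
  meta_path <- paste0(path, ".meta.json")
  m <- if (sidecar && file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  kind <- m$kind %||% "envelope"
  log <- m$processing_log
  if (is.data.frame(log)) log <- lapply(seq_len(nrow(log)), function(i) as.list(log[i, ]))
  ppg_trace(df$value_mV, m$rate %||% rate, kind,
    f_carrier = m$f_carrier,
    log = log %||% list(),
    transient = m$transient %||% 0L
  )
}

#' Read and write traces as float WAV
#'
#' Minimal mono IEEE-float (32-bit) RIFF/WAVE container — the natural
#' compact format for a 96 kHz single-channel stream. Values are stored
#' in mV without rescaling.
#'
#' @param trace a [ppg_trace()].
#' @param path file path.
#' @param f_carrier carrier frequency to attach on read (raw traces).
#' @param kind trace kind to assume on read.
#' @return `write_trace_wav()` the path invisibly; `read_trace_wav()` a
#'   [ppg_trace()].
#' @export
write_trace_wav <- function(trace, path) {
  x <- trace_values(trace)
  rate <- round(trace_rate(trace))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little") # IEEE float
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_trace_wav
#' @export
read_trace_wav <- function(path, f_carrier = NULL, kind = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAVE file.")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) abort("not a RIFF/WAVE file.")
  rate <- NA_real_
  values <- NULL
  fmt <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, raw(), n = sz - 8))
    } else if (id == "data") {
      if (fmt != 3L) abort("only IEEE-float WAV is supported.")
      values <- readBin(con, numeric(), n = sz %/% 4, size = 4, endian = "little")
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
    if (!is.null(values)) break
  }
  if (is.null(values)) abort("no data chunk found.")
  kind <- kind %||% if (!is.null(f_carrier)) "raw" else "envelope"
  ppg_trace(values, rate, kind, f_carrier = f_carrier)
}

#' Run configuration
#'
#' All tunable pipeline parameters plus the master seed, serializable to
#' and from JSON without loss. Unknown keys in a configuration file are
#' rejected rather than silently ignored.
#'
#' @param seed master seed.
#' @param n_viable,n_nonviable batch composition (defaults 15 and 5).
#' @param arrangement preset name.
#' @param days incubation days for monitoring runs.
#' @param format trace container, `"csv"` or `"wav"`.
#' @param sim a [sim_config()] parameter list.
#' @param n_cycles,kernel_length,lp_order,lp_cutoff,stft_window,stft_hop
#'   pipeline parameters.
#' @param thresholds a [viability_thresholds()] parameter list.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_viable = 15L, n_nonviable = 5L,
                       arrangement = "c", days = 10:14, format = "csv",
                       sim = sim_config(seed = seed), n_cycles = 20,
                       kernel_length = 10, lp_order = 100, lp_cutoff = 7,
                       stft_window = 255, stft_hop = 1,
                       thresholds = viability_thresholds()) {
  structure(
    list(
      seed = as.integer(seed), n_viable = as.integer(n_viable),
      n_nonviable = as.integer(n_nonviable), arrangement = arrangement,
      days = as.integer(days), format = format,
      sim = unclass(sim), n_cycles = n_cycles,
      kernel_length = kernel_length, lp_order = lp_order,
      lp_cutoff = lp_cutoff, stft_window = stft_window,
      stft_hop = stft_hop, thresholds = unclass(thresholds)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @param x a `run_config` (write) — ignored on read.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  template <- run_config()
  unknown <- setdiff(names(raw), names(template))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  for (blk in c("sim", "thresholds")) {
    if (!is.null(raw[[blk]])) {
      bad <- setdiff(names(raw[[blk]]), names(template[[blk]]))
      if (length(bad)) {
        abort(paste0("unknown config keys in ", blk, ": ", paste(bad, collapse = ", ")))
      }
      template[[blk]][names(raw[[blk]])] <- raw[[blk]]
    }
  }
  flat <- setdiff(names(raw), c("sim", "thresholds"))
  template[flat] <- raw[flat]
  template$seed <- as.integer(template$seed)
  template$sim$seed <- as.integer(template$sim$seed %||% template$seed)
  template
}

#' Write a batch manifest
#'
#' @param entries tibble with at least `embryo_id`, `file` and whatever
#'   labels/parameters accompany each trace.
#' @param path manifest JSON path.
#' @param config the [run_config()] that produced the batch.
#' @return The path, invisibly.
#' @export
write_manifest <- function(entries, path, config = NULL) {
  jsonlite::write_json(
    list(config = if (!is.null(config)) unclass(config), entries = entries),
    path,
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(config = m$config, entries = as_tibble(m$entries))
}
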