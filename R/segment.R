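# Lazy segment access: translate time ranges to record-aligned byte ranges,
# read through a loading strategy, de-interleave and calibrate.

.t_eps <- 1e-9

#' A half-open time range in seconds from recording start
#'
#' @param start_s start offset (>= 0).
#' @param end_s end offset (> `start_s`); the range is `[start_s, end_s)`.
#' @export
time_range <- function(start_s, end_s) {
  if (!is.finite(start_s) || !is.finite(end_s) || end_s <= start_s || start_s < 0) {
    edf_error("edf_empty_range_error",
              sprintf("invalid time range [%s, %s)", start_s, end_s))
  }
  structure(list(start_s = start_s, end_s = end_s), class = "edf_time_range")
}

#' Clip a time range to the recording bounds
#' @param t an `edf_time_range`.
#' @param total_s recording duration in seconds.
#' @export
clip_time_range <- function(t, total_s) {
  s <- max(t$start_s, 0)
  e <- min(t$end_s, total_s)
  if (e <= s) {
    edf_error("edf_empty_range_error",
              sprintf("time range [%s, %s) is empty after clipping to [0, %s)",
                      t$start_s, t$end_s, total_s))
  }
  time_range(s, e)
}

record_span <- function(t, record_duration_s) {
  first <- floor(t$start_s / record_duration_s + .t_eps)
  last <- ceiling(t$end_s / record_duration_s - .t_eps) - 1
  c(first = first, last = last)
}

#' Translate a time range into its covering byte range
#'
#' Returns the smallest record-aligned byte range covering `t`:
#' the requested range is expanded outward to record boundaries
#' (`first = floor(start/dur)`, `last = ceil(end/dur) - 1`), never shrunk,
#' so no requested sample is dropped.
#'
#' @param t an `edf_time_range` (clipped to the recording).
#' @param rec recording header.
#' @param sigs list of signal headers.
#' @return a list with `offset`, `length` (bytes), and the covered
#'   `first_record`/`last_record`.
#' @export
time_range_to_byte_range <- function(t, rec, sigs) {
  t <- clip_time_range(t, total_duration_s(rec))
  rs <- record_size_bytes(sigs)
  span <- record_span(t, rec$record_duration_s)
  structure(list(
    offset = rec$header_bytes + span[["first"]] * rs,
    length = (span[["last"]] - span[["first"]] + 1) * rs,
    first_record = span[["first"]],
    last_record = span[["last"]]
  ), class = "edf_byte_range")
}

#' Open an EDF recording for lazy access
#'
#' Reads only the headers (two strategy reads); signal data stays on the
#' backing source until requested through [read_segment()] or [get_data()].
#'
#' @param input local path, `http(s)://` URL, or an `edf_loading_strategy`.
#' @return an `edf_recording` handle (headers + strategy).
#' @export
open_edf <- function(input) {
  strategy <- if (inherits(input, "edf_loading_strategy")) input else resolve_strategy(input)
  static <- read_bytes(strategy, 0, 256)
  ns_txt <- rawToChar(static[253:256])
  ns <- as.integer(edf_num(ns_txt, "num_signals", integer = TRUE))
  full <- c(static, read_bytes(strategy, 256, 256 * ns))
  h <- parse_headers(full)
  structure(list(
    strategy = strategy,
    rec = h$rec,
    sigs = h$sigs,
    record_size = record_size_bytes(h$sigs)
  ), class = "edf_recording")
}

#' @export
print.edf_recording <- function(x, ...) {
  print(x$rec)
  cat(sprintf("  source: %s\n", x$strategy$description))
  invisible(x)
}

#' Construct a channel series (flat min/max representation)
#'
#' One flat array per component rather than one container per sample: this is
#' the memory-optimized layout (`timestamp, min, max` triples).  For
#' uncompressed data `min_values == max_values`.
#'
#' @param channel_index 1-based signal index in the recording.
#' @param timestamps_ms strictly increasing absolute epoch milliseconds.
#' @param min_values,max_values physical-unit values, same length as
#'   `timestamps_ms`, `min <= max` elementwise.
#' @param label signal label.
#' @param frequency_per_s bucket rate when min-max compressed, else `NULL`.
#' @export
channel_series <- function(channel_index, timestamps_ms, min_values, max_values,
                           label = NULL, frequency_per_s = NULL) {
  n <- length(timestamps_ms)
  stopifnot(length(min_values) == n, length(max_values) == n)
  if (n > 1 && any(diff(timestamps_ms) <= 0)) {
    stop("timestamps_ms must be strictly increasing")
  }
  if (any(min_values > max_values + 1e-12)) {
    stop("min_values must be <= max_values")
  }
  structure(list(
    channel_index = channel_index,
    label = label,
    timestamps_ms = as.numeric(timestamps_ms),
    min_values = as.numeric(min_values),
    max_values = as.numeric(max_values),
    frequency_per_s = frequency_per_s
  ), class = "edf_channel_series")
}

#' @export
print.edf_channel_series <- function(x, ...) {
  cat(sprintf("channel %s [%s]: %d point(s)%s\n", x$channel_index,
              if (is.null(x$label)) "?" else x$label, length(x$timestamps_ms),
              if (is.null(x$frequency_per_s)) "" else
                sprintf(", min-max @ %g/s", x$frequency_per_s)))
  invisible(x)
}

decode_records <- function(raw, sigs) {
  spr <- vapply(sigs, function(s) s$samples_per_record, integer(1))
  rec_samples <- sum(spr)
  stopifnot(length(raw) %% (2L * rec_samples) == 0)
  nrec <- length(raw) %/% (2L * rec_samples)
  d <- readBin(raw, "integer", n = nrec * rec_samples, size = 2L,
               signed = TRUE, endian = "little")
  m <- matrix(d, nrow = rec_samples, ncol = nrec)
  ends <- cumsum(spr)
  starts <- ends - spr + 1L
  lapply(seq_along(sigs), function(c) as.vector(m[starts[c]:ends[c], , drop = FALSE]))
}

#' Read a calibrated segment of signal data
#'
#' The requested time range is expanded to covering record boundaries, the
#' corresponding bytes are fetched (from the prefetch cache when one is given
#' and covers the span, otherwise through the strategy), de-interleaved from
#' the record-packed layout into per-channel flat arrays, calibrated to
#' physical units, and trimmed to exactly `[start_s, end_s)`.
#'
#' @param x an `edf_recording` from [open_edf()].
#' @param t an `edf_time_range` (or numeric `c(start_s, end_s)`).
#' @param channels integer indices of signals to return (default: all
#'   ordinary signal channels; EDF+ annotation channels are skipped).
#' @param cache optional [segment_cache()].
#' @return list of `edf_channel_series` (uncompressed: `min == max`),
#'   timestamps in absolute epoch milliseconds.
#' @export
read_segment <- function(x, t, channels = NULL, cache = NULL) {
  if (is.numeric(t)) t <- time_range(t[1], t[2])
  t <- clip_time_range(t, total_duration_s(x$rec))
  br <- time_range_to_byte_range(t, x$rec, x$sigs)
  raw <- NULL
  if (!is.null(cache)) {
    raw <- cache_get_records(cache, br$first_record, br$last_record)
  }
  if (is.null(raw)) {
    raw <- read_bytes(x$strategy, br$offset, br$length)
  }
  series <- decode_records(raw, x$sigs)
  if (is.null(channels)) {
    channels <- which(!vapply(x$sigs, is_annotation_channel, logical(1)))
  }
  t0_ms <- start_epoch_ms(x$rec)
  rec0_s <- br$first_record * x$rec$record_duration_s
  lapply(channels, function(c) {
    sig <- x$sigs[[c]]
    fs <- sampling_rate_hz(sig, x$rec)
    v <- digital_to_physical(series[[c]], sig)
    # sample i (0-based, within loaded span) sits at rec0_s + i/fs;
    # keep exactly those inside [start_s, end_s)
    i0 <- max(0, ceiling((t$start_s - rec0_s) * fs - .t_eps))
    i1 <- ceiling((t$end_s - rec0_s) * fs - .t_eps) - 1
    i1 <- min(i1, length(v) - 1)
    idx <- if (i1 < i0) integer(0) else seq.int(i0, i1)
    ts <- t0_ms + (rec0_s + idx / fs) * 1000
    vv <- v[idx + 1]
    channel_series(c, ts, vv, vv, label = sig$label)
  })
}
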