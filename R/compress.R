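# Min-max decimation to display resolution.
#
# When the signal's sampling rate exceeds the horizontal resolution of the
# display, all samples falling in one pixel column paint the same vertical
# extent; drawing only the per-column minimum and maximum gives the same
# picture.  The frequency parameter f is the maximum number of min-max
# buckets per second; stored values per second are then 2f, so the fraction
# of samples eliminated for a source rate fs is 1 - 2f/fs.

#' Percentage of samples eliminated by min-max decimation
#'
#' A source at `fs` samples/s reduced to `f` buckets/s stores `2 f` values
#' per second (one min and one max per bucket), eliminating
#' `max(0, 1 - min(1, 2 f / fs)) * 100` percent of the samples.
#' E.g. a 500 Hz signal drawn at 40 columns per second keeps 80 of 500
#' values: a space gain of 84%.
#'
#' @param fs source sampling rate (Hz).
#' @param f bucket rate (buckets per second).
#' @return percentage in `[0, 100]`.
#' @export
compression_gain <- function(fs, f) {
  stopifnot(fs > 0, f > 0)
  max(0, 1 - min(1, 2 * f / fs)) * 100
}

# Bucket classification tolerance: absolute epoch-ms timestamps carry a
# double-precision quantization of ~2.4e-4 ms, so a sample nominally on a
# bucket boundary can land just below it.  1 us is far above that error and
# far below any genuine sample offset at biosignal rates.
.bucket_eps_ms <- 1e-3

bucket_minmax <- function(timestamps_ms, mins, maxs, f, anchor_ms) {
  k <- floor((timestamps_ms - anchor_ms + .bucket_eps_ms) * f / 1000)
  ends <- cumsum(rle(k)$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  n <- length(ends)
  out_min <- numeric(n); out_max <- numeric(n); out_k <- numeric(n)
  for (g in seq_len(n)) {
    i <- starts[g]:ends[g]
    out_min[g] <- min(mins[i])
    out_max[g] <- max(maxs[i])
    out_k[g] <- k[starts[g]]
  }
  list(timestamps_ms = anchor_ms + out_k * 1000 / f,
       min_values = out_min, max_values = out_max)
}

#' Min-max compress a channel series
#'
#' Buckets the series at rate `f`: bucket `k` spans
#' `[anchor + k/f, anchor + (k+1)/f)` seconds; each non-empty bucket yields
#' one `(bucket start timestamp, min, max)` triple; empty buckets are
#' omitted.  Already-compressed input is re-bucketed over its min and max
#' arrays, so compressing at the same `f` is a no-op.
#'
#' @param series an `edf_channel_series`.
#' @param f bucket rate per second (> 0).
#' @param anchor_ms bucket grid origin in epoch ms (default: first timestamp).
#' @return an `edf_channel_series` with `frequency_per_s = f`.
#' @export
minmax_compress <- function(series, f, anchor_ms = NULL) {
  if (!is.finite(f) || f <= 0) {
    edf_error("edf_invalid_frequency_error", "frequency must be a positive number")
  }
  if (length(series$timestamps_ms) == 0) {
    out <- series
    out$frequency_per_s <- f
    return(out)
  }
  if (is.null(anchor_ms)) anchor_ms <- series$timestamps_ms[1]
  b <- bucket_minmax(series$timestamps_ms, series$min_values, series$max_values,
                     f, anchor_ms)
  channel_series(series$channel_index, b$timestamps_ms, b$min_values,
                 b$max_values, label = series$label, frequency_per_s = f)
}

#' Read signal data for a time range, optionally min-max compressed
#'
#' The central access method: takes a time range and optionally a frequency
#' `f` (maximum buckets per second in the result).  Without `f` the result
#' is uncompressed (`min == max`).  With `f`, each channel whose sampling
#' rate exceeds `f` is independently bucketed on a grid anchored at the
#' (clipped) range start; channels sampled at or below `f` pass through
#' unchanged.
#'
#' @inheritParams read_segment
#' @param frequency optional bucket rate `f` per second.
#' @return list of `edf_channel_series`.
#' @export
get_data <- function(x, t, frequency = NULL, channels = NULL, cache = NULL) {
  if (!is.null(frequency) && (!is.finite(frequency) || frequency <= 0)) {
    edf_error("edf_invalid_frequency_error", "frequency must be a positive number")
  }
  if (is.numeric(t)) t <- time_range(t[1], t[2])
  t <- clip_time_range(t, total_duration_s(x$rec))
  series <- read_segment(x, t, channels = channels, cache = cache)
  if (is.null(frequency)) return(series)
  anchor <- start_epoch_ms(x$rec) + t$start_s * 1000
  lapply(series, function(s) {
    fs <- sampling_rate_hz(x$sigs[[s$channel_index]], x$rec)
    if (fs <= frequency) s else minmax_compress(s, frequency, anchor_ms = anchor)
  })
}
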