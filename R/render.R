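# Static window rendering.
#
# The desk-tool counterpart of an interactive viewer: one stacked panel per
# channel, each pixel column drawn as the vertical extent of the samples
# that fall into it.  At a column rate of width/duration buckets per
# second, min-max decimated data paints exactly the same extents as the
# raw samples -- the property the compression is built on.

#' Describe a rendering window
#'
#' @param start_s window start in seconds from recording start.
#' @param duration_s window length in seconds; the presets of a typical
#'   viewer are 30 s (one epoch), 5 min, and the full recording.
#' @param width_px horizontal image resolution.
#' @param preset `"30s"`, `"5min"` or `"full"`; overrides `duration_s`
#'   (`"full"` needs `total_s`).
#' @param total_s recording duration (for `preset = "full"`).
#' @export
view_spec <- function(start_s = 0, duration_s = 30, width_px = 1200,
                      preset = NULL, total_s = NULL) {
  if (!is.null(preset)) {
    duration_s <- switch(match.arg(preset, c("30s", "5min", "full")),
                         "30s" = 30,
                         "5min" = 300,
                         "full" = {
                           if (is.null(total_s)) stop("preset 'full' needs total_s")
                           total_s - start_s
                         })
  }
  stopifnot(duration_s > 0, width_px >= 1)
  structure(list(start_s = start_s, duration_s = duration_s,
                 width_px = as.integer(width_px)),
            class = "edf_view_spec")
}

#' Pixel columns available per second of data
#' @param width_px horizontal resolution.
#' @param duration_s displayed duration.
#' @export
columns_per_second <- function(width_px, duration_s) width_px / duration_s

#' Whole samples sharing one pixel column
#'
#' At `fs` samples/s and `columns_per_second(width_px, duration_s)` columns,
#' `floor(fs / cols)` whole samples overlay in the same column.
#' @param fs sampling rate in Hz.
#' @inheritParams columns_per_second
#' @export
samples_per_column <- function(fs, width_px, duration_s) {
  floor(fs / columns_per_second(width_px, duration_s))
}

#' Lower latency bound from the display refresh rate
#'
#' A monitor refreshing at `hz` cannot show an update faster than one frame
#' period, `floor(1000 / hz)` whole milliseconds (16 ms at 60 Hz).
#' @param hz display refresh rate.
#' @export
min_frame_period_ms <- function(hz) floor(1000 / hz)

#' Per-pixel-column vertical extents for a window
#'
#' For each requested channel, computes the min/max of the samples falling
#' into each of the `width_px` columns of the window.  `from = "raw"`
#' buckets the uncompressed samples directly; `from = "compressed"` first
#' min-max decimates at `f = width_px / duration_s` and derives the extents
#' from the pairs.  Both routes yield identical extents.
#'
#' @param x an `edf_recording`.
#' @param view an [view_spec()].
#' @param channels signal indices (default: all ordinary channels).
#' @param from `"raw"` or `"compressed"`.
#' @param cache optional [segment_cache()].
#' @return named list (by channel label) of `2 x width_px` matrices
#'   (rows `min`, `max`), `NA` for empty columns.
#' @export
column_extents <- function(x, view, channels = NULL, from = c("raw", "compressed"),
                           cache = NULL) {
  from <- match.arg(from)
  t <- clip_time_range(time_range(view$start_s, view$start_s + view$duration_s),
                       total_duration_s(x$rec))
  f <- view$width_px / view$duration_s
  series <- if (from == "raw") {
    read_segment(x, t, channels = channels, cache = cache)
  } else {
    get_data(x, t, frequency = f, channels = channels, cache = cache)
  }
  anchor <- start_epoch_ms(x$rec) + t$start_s * 1000
  lapply(stats::setNames(series, vapply(series, `[[`, character(1), "label")),
         function(s) {
           ext <- matrix(NA_real_, nrow = 2, ncol = view$width_px,
                         dimnames = list(c("min", "max"), NULL))
           if (length(s$timestamps_ms) == 0) return(ext)
           col <- floor((s$timestamps_ms - anchor + 1e-3) * f / 1000)
           keep <- col >= 0 & col < view$width_px
           b <- bucket_minmax(s$timestamps_ms[keep], s$min_values[keep],
                              s$max_values[keep], f, anchor)
           j <- as.integer(round((b$timestamps_ms - anchor) * f / 1000)) + 1L
           ext["min", j] <- b$min_values
           ext["max", j] <- b$max_values
           ext
         })
}

#' Render a window of a recording to a PNG image
#'
#' One stacked panel per channel; each pixel column is drawn as a vertical
#' segment spanning the column's true data extent, so the picture from
#' min-max decimated input equals the one from raw input.  Events are
#' overlaid as translucent spans.  Output is deterministic for fixed
#' inputs.  Only the covering byte range of the window is read (lazy).
#'
#' @param x an `edf_recording`.
#' @param view an [view_spec()].
#' @param out output PNG path.
#' @param events optional `edf_event_set` to overlay.
#' @param channels signal indices (default: all ordinary channels).
#' @param panel_height_px height per channel panel.
#' @param cache optional [segment_cache()].
#' @return invisibly, the list of column extents that were drawn.
#' @export
render_window <- function(x, view, out, events = NULL, channels = NULL,
                          panel_height_px = 100, cache = NULL) {
  ext <- column_extents(x, view, channels = channels, from = "compressed",
                        cache = cache)
  nch <- length(ext)
  if (nch == 0) edf_error("edf_render_error", "no channels to render")
  grDevices::png(out, width = view$width_px, height = panel_height_px * nch)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(nch, 1), mar = c(0.2, 4, 0.2, 0.5), xaxs = "i")
  t0 <- view$start_s
  t1 <- view$start_s + view$duration_s
  ev <- if (!is.null(events)) as.data.frame(events) else NULL
  rel_s <- function(ms) (ms - start_epoch_ms(x$rec)) / 1000
  for (nm in names(ext)) {
    e <- ext[[nm]]
    mid <- mean(c(e["min", ], e["max", ]), na.rm = TRUE)
    half <- max(abs(range(e, na.rm = TRUE) - mid), .Machine$double.eps)
    graphics::plot(NA, xlim = c(t0, t1), ylim = c(mid - half, mid + half),
                   xlab = "", ylab = nm, xaxt = "n", yaxt = "n", bty = "o",
                   cex.lab = 0.8)
    if (!is.null(ev) && nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        a <- rel_s(ev$start_ms[i])
        b <- if (is.na(ev$end_ms[i])) a + 0.25 else rel_s(ev$end_ms[i])
        graphics::rect(a, mid - half, b, mid + half,
                       col = grDevices::rgb(0.2, 0.4, 1, 0.25), border = NA)
      }
    }
    cols <- which(!is.na(e["min", ]))
    cx <- t0 + (cols - 0.5) * view$duration_s / view$width_px
    graphics::segments(cx, e["min", cols], cx, e["max", cols], lwd = 1)
    flat <- cols[e["min", cols] == e["max", cols]]
    if (length(flat) > 0) {
      graphics::points(t0 + (flat - 0.5) * view$duration_s / view$width_px,
                       e["min", flat], pch = ".", cex = 0.5)
    }
  }
  invisible(ext)
}

#' Header report for a recording
#'
#' Formats the static and dynamic header fields, per-channel sampling rates
#' and harmonized label suggestions.  The report depends only on the file
#' content, never on the source path, so it is identical across loading
#' strategies.
#'
#' @param x an `edf_recording` (or a path/URL, which is opened).
#' @param table harmonization table for label suggestions.
#' @return character vector of report lines.
#' @export
edf_info <- function(x, table = load_harmonization_table()) {
  if (!inherits(x, "edf_recording")) x <- open_edf(x)
  rec <- x$rec
  labels <- vapply(x$sigs, `[[`, character(1), "label")
  h <- harmonize(labels, table)
  lines <- c(
    sprintf("version:          %s", rec$version),
    sprintf("patient:          %s", rec$patient_id),
    sprintf("recording:        %s", rec$recording_id),
    sprintf("start:            %s %s (UTC)", format(rec$start_date),
            edf_format_time(rec$start_time)),
    sprintf("records:          %d x %g s", rec$num_records, rec$record_duration_s),
    sprintf("total duration:   %g s", total_duration_s(rec)),
    sprintf("header bytes:     %d", rec$header_bytes),
    sprintf("signals:          %d", rec$num_signals),
    ""
  )
  for (i in seq_along(x$sigs)) {
    s <- x$sigs[[i]]
    note <- if (is_annotation_channel(s)) {
      "[annotations channel]"
    } else if (h$matched[i] && h$standard[i] != labels[i]) {
      sprintf("-> %s", h$standard[i])
    } else if (!h$matched[i]) {
      "[no standard match]"
    } else ""
    lines <- c(lines, sprintf(
      "  %2d  %-16s %8g Hz  %8s  phys [%g, %g]  dig [%d, %d]  %s",
      i, s$label, sampling_rate_hz(s, rec), s$physical_dimension,
      s$physical_min, s$physical_max, s$digital_min, s$digital_max, note))
  }
  lines
}
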