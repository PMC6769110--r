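# Viewport prefetch cache.
#
# The viewer keeps a buffer of two viewport widths left and right of the
# currently shown span preloaded; scrolling inside the buffered span is then
# served without touching the backing source, and data outside the span is
# evicted as dispensable.  The cache holds one contiguous record-aligned
# range of raw record bytes.

#' Create a segment cache for a recording
#'
#' @param x an `edf_recording`.
#' @param prefetch_multiplier how many viewport widths to prefetch on each
#'   side of the viewport (default 2).
#' @return an `edf_segment_cache` (mutable handle).
#' @export
segment_cache <- function(x, prefetch_multiplier = 2L) {
  stopifnot(inherits(x, "edf_recording"), prefetch_multiplier >= 0)
  cache <- new.env(parent = emptyenv())
  cache$recording <- x
  cache$prefetch_multiplier <- prefetch_multiplier
  cache$first_record <- NA_real_   # covered record span, inclusive
  cache$last_record <- NA_real_
  cache$raw <- raw(0)
  class(cache) <- "edf_segment_cache"
  cache
}

#' @export
print.edf_segment_cache <- function(x, ...) {
  if (is.na(x$first_record)) {
    cat("<segment cache: empty>\n")
  } else {
    cat(sprintf("<segment cache: records %g..%g (%d bytes)>\n",
                x$first_record, x$last_record, length(x$raw)))
  }
  invisible(x)
}

cache_read_records <- function(cache, first, last) {
  x <- cache$recording
  read_bytes(x$strategy,
             x$rec$header_bytes + first * x$record_size,
             (last - first + 1) * x$record_size)
}

# raw record bytes for [first, last] if fully covered, else NULL (miss)
cache_get_records <- function(cache, first, last) {
  if (is.na(cache$first_record) ||
      first < cache$first_record || last > cache$last_record) {
    return(NULL)
  }
  rs <- cache$recording$record_size
  a <- (first - cache$first_record) * rs
  cache$raw[(a + 1):(a + (last - first + 1) * rs)]
}

#' Span covered by the cache, as a time range in seconds (or NULL)
#' @param cache an `edf_segment_cache`.
#' @export
cache_coverage <- function(cache) {
  if (is.na(cache$first_record)) return(NULL)
  dur <- cache$recording$rec$record_duration_s
  time_range(cache$first_record * dur, (cache$last_record + 1) * dur)
}

#' Ensure the prefetch window around a viewport is cached
#'
#' For a viewport `t` of width `W = end - start`, makes the cache cover the
#' record-aligned span `[start - mW, end + mW]` (m = prefetch multiplier),
#' clipped to the recording, issuing at most one strategy read per missing
#' side; data outside the span is evicted.  Repeated calls with the same
#' viewport are no-ops.  On a strategy failure the cache is left unchanged.
#'
#' @param cache an `edf_segment_cache`.
#' @param t the viewport as an `edf_time_range` or numeric `c(start_s, end_s)`.
#' @return the cache, invisibly.
#' @export
ensure_window <- function(cache, t) {
  if (is.numeric(t)) t <- time_range(t[1], t[2])
  x <- cache$recording
  total <- total_duration_s(x$rec)
  t <- clip_time_range(t, total)
  w <- t$end_s - t$start_s
  m <- cache$prefetch_multiplier
  span <- clip_time_range(time_range(max(0, t$start_s - m * w),
                                     min(total, t$end_s + m * w)), total)
  rs <- record_span(span, x$rec$record_duration_s)
  first <- rs[["first"]]; last <- rs[["last"]]

  if (!is.na(cache$first_record) &&
      cache$first_record <= first && cache$last_record >= last) {
    # covered; trim anything outside the span (eviction)
    keep <- cache_get_records(cache, first, last)
    cache$raw <- keep
    cache$first_record <- first
    cache$last_record <- last
    return(invisible(cache))
  }

  if (is.na(cache$first_record) ||
      last < cache$first_record - 1 || first > cache$last_record + 1) {
    # disjoint from current contents: one fresh read, then replace
    raw <- cache_read_records(cache, first, last)
    cache$raw <- raw
  } else {
    left <- if (first < cache$first_record) {
      cache_read_records(cache, first, cache$first_record - 1)
    } else raw(0)
    right <- if (last > cache$last_record) {
      cache_read_records(cache, cache$last_record + 1, last)
    } else raw(0)
    mid <- cache_get_records(cache, max(first, cache$first_record),
                             min(last, cache$last_record))
    cache$raw <- c(left, mid, right)
  }
  cache$first_record <- first
  cache$last_record <- last
  invisible(cache)
}

#' Fetch cached bytes for a time range, or report a miss
#'
#' @param cache an `edf_segment_cache`.
#' @param t time range.
#' @return raw record bytes covering `t` if cached, else `NULL`.
#' @export
get_cached <- function(cache, t) {
  if (is.numeric(t)) t <- time_range(t[1], t[2])
  x <- cache$recording
  t <- clip_time_range(t, total_duration_s(x$rec))
  rs <- record_span(t, x$rec$record_duration_s)
  cache_get_records(cache, rs[["first"]], rs[["last"]])
}
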