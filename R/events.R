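# Event and annotation model with a JSON interchange format.
#
# There is no standard text-based export format for biosignal events; the
# embedded annotation channels of EDF+ are binary, size-limited and bound to
# the large data file.  Events are therefore interchanged as JSON: one
# object whose keys are UNIX timestamps in milliseconds and whose values
# describe the event.  Two dialects are supported:
#   literal  -- value is the label string only (point events; lossless for
#               events without end or channel)
#   extended -- value is an object {"label": ..., "end_ms": ..., "channel": ...}
# Dialects are auto-detected on import.

.sleep_stages <- c("W", "N1", "N2", "N3", "R")
.epoch_ms <- 30000

#' Construct an event set
#'
#' An ordered collection of labeled time points/ranges (apnea episodes,
#' artifacts, sleep stages, ...), kept sorted by start time (ties broken by
#' label) through every edit.
#'
#' @param start_ms absolute epoch milliseconds (numeric vector).
#' @param label event labels.
#' @param end_ms optional end timestamps (`NA` for point events; otherwise
#'   `> start_ms`).
#' @param channel optional channel labels.
#' @param source optional provenance tags (e.g. `"external"`).
#' @return an `edf_event_set` (data frame).
#' @export
event_set <- function(start_ms = numeric(0), label = character(0),
                      end_ms = NA_real_, channel = NA_character_,
                      source = NA_character_) {
  n <- length(start_ms)
  df <- data.frame(start_ms = as.numeric(start_ms),
                   end_ms = rep_len(as.numeric(end_ms), n),
                   label = rep_len(as.character(label), n),
                   channel = rep_len(as.character(channel), n),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  bad <- !is.na(df$end_ms) & df$end_ms <= df$start_ms
  if (any(bad)) {
    edf_error("edf_event_range_error", "end_ms must be > start_ms")
  }
  sort_events(df)
}

sort_events <- function(df) {
  df <- df[order(df$start_ms, df$label), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("edf_event_set", "data.frame")
  df
}

#' Add an event
#' @param es an `edf_event_set`.
#' @param start_ms,label,end_ms,channel,source event fields.
#' @export
add_event <- function(es, start_ms, label, end_ms = NA_real_,
                      channel = NA_character_, source = NA_character_) {
  one <- event_set(start_ms, label, end_ms, channel, source)
  sort_events(rbind(as.data.frame(es), as.data.frame(one)))
}

find_event <- function(es, i) {
  if (length(i) != 1 || is.na(i) || i < 1 || i > nrow(es)) {
    edf_error("edf_unknown_event_error", sprintf("no event with index %s", i))
  }
  as.integer(i)
}

#' Remove an event by index
#' @param es an `edf_event_set`.
#' @param i row index (in sorted order).
#' @export
remove_event <- function(es, i) {
  i <- find_event(es, i)
  sort_events(as.data.frame(es)[-i, , drop = FALSE])
}

#' Move an event in time, preserving its duration
#' @param es an `edf_event_set`.
#' @param i row index.
#' @param delta_ms shift in milliseconds.
#' @export
move_event <- function(es, i, delta_ms) {
  i <- find_event(es, i)
  df <- as.data.frame(es)
  df$start_ms[i] <- df$start_ms[i] + delta_ms
  df$end_ms[i] <- df$end_ms[i] + delta_ms
  sort_events(df)
}

#' Resize a range event
#'
#' Changes one bound, keeping the other fixed.  The resulting range must be
#' non-empty.
#'
#' @param es an `edf_event_set`.
#' @param i row index.
#' @param new_start_ms,new_end_ms new bound (give exactly one).
#' @export
resize_event <- function(es, i, new_start_ms = NULL, new_end_ms = NULL) {
  i <- find_event(es, i)
  df <- as.data.frame(es)
  if (!is.null(new_start_ms)) df$start_ms[i] <- as.numeric(new_start_ms)
  if (!is.null(new_end_ms)) df$end_ms[i] <- as.numeric(new_end_ms)
  if (!is.na(df$end_ms[i]) && df$end_ms[i] <= df$start_ms[i]) {
    edf_error("edf_event_range_error", "resize would invert or empty the range")
  }
  sort_events(df)
}

event_key <- function(df) {
  paste(sprintf("%.0f", df$start_ms),
        ifelse(is.na(df$end_ms), "", sprintf("%.0f", df$end_ms)),
        df$label, ifelse(is.na(df$channel), "", df$channel), sep = "\x1f")
}

#' Export an event set as JSON
#'
#' Keys are decimal `start_ms` strings emitted in ascending numeric order,
#' so export is deterministic.  The literal dialect stores only the label
#' and drops `end_ms`/`channel` (documented lossiness); the extended dialect
#' stores a structured value.  Since a JSON object cannot hold two events at
#' one timestamp, colliding start keys are nudged by +1 ms with a warning.
#'
#' @param es an `edf_event_set`.
#' @param dialect `"literal"` or `"extended"`.
#' @return a JSON string.
#' @export
export_events <- function(es, dialect = c("literal", "extended")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(es)
  keys <- df$start_ms
  if (anyDuplicated(keys)) {
    for (i in seq_along(keys)) {
      while (keys[i] %in% keys[seq_len(i - 1)]) keys[i] <- keys[i] + 1
    }
    warning("duplicate start timestamps nudged by +1 ms to fit the keyed object format")
  }
  o <- order(keys)
  vals <- if (dialect == "literal") {
    as.list(df$label[o])
  } else {
    lapply(o, function(i) {
      v <- list(label = df$label[i])
      if (!is.na(df$end_ms[i])) v$end_ms <- df$end_ms[i]
      if (!is.na(df$channel[i])) v$channel <- df$channel[i]
      if (!is.na(df$source[i])) v$source <- df$source[i]
      v
    })
  }
  names(vals) <- sprintf("%.0f", keys[o])
  if (length(vals) == 0) return("{}")
  as.character(jsonlite::toJSON(vals, auto_unbox = TRUE, digits = NA))
}

#' Import an event set from JSON (dialect auto-detected)
#'
#' @param text JSON text: one object keyed by decimal millisecond
#'   timestamps; string values are the literal dialect, object values the
#'   extended dialect.
#' @param source provenance tag attached to the imported events.
#' @return an `edf_event_set`.
#' @export
import_events <- function(text, source = NA_character_) {
  obj <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) {
                    edf_error("edf_event_json_error",
                              paste("malformed JSON:", conditionMessage(e)))
                  })
  if (!is.list(obj) || (length(obj) > 0 && is.null(names(obj)))) {
    edf_error("edf_event_json_error", "expected a JSON object keyed by timestamps")
  }
  if (length(obj) == 0) return(event_set())
  keys <- names(obj)
  if (any(!grepl("^-?[0-9]+$", keys))) {
    edf_error("edf_event_json_error", "non-numeric timestamp key in event JSON")
  }
  start <- as.numeric(keys)
  lab <- character(length(obj)); end <- rep(NA_real_, length(obj))
  chan <- rep(NA_character_, length(obj)); src <- rep(source, length(obj))
  for (i in seq_along(obj)) {
    v <- obj[[i]]
    if (is.character(v) && length(v) == 1) {
      lab[i] <- v
    } else if (is.list(v) && !is.null(v$label)) {
      lab[i] <- v$label
      if (!is.null(v$end_ms)) end[i] <- as.numeric(v$end_ms)
      if (!is.null(v$channel)) chan[i] <- v$channel
      if (!is.null(v$source) && is.na(source)) src[i] <- v$source
    } else {
      edf_error("edf_event_json_error",
                sprintf("value for key %s is neither a label string nor an event object",
                        keys[i]))
    }
  }
  event_set(start, lab, end, chan, src)
}

#' Merge externally produced events into a set
#'
#' Analysis pipelines (artifact detectors, apnea detectors, ...) return
#' events in the same JSON dialects; they are merged into the working set,
#' deduplicated on `(start_ms, end_ms, label, channel)` while the source
#' tag is retained.  Merging a set with itself is a no-op.
#'
#' @param text JSON text of the external events.
#' @param es the working `edf_event_set`.
#' @param source provenance tag for the ingested events.
#' @export
ingest_external_events <- function(text, es, source = "external") {
  ext <- import_events(text, source = source)
  all <- rbind(as.data.frame(es), as.data.frame(ext))
  all <- all[!duplicated(event_key(all)), , drop = FALSE]
  sort_events(all)
}

#' Validate an event set as a hypnogram
#'
#' Sleep-stage scoring uses range events with the reserved labels W, N1,
#' N2, N3, R, one per 30 s epoch.  A valid hypnogram covers the whole
#' recording with non-overlapping 30 s epochs aligned to the recording
#' start.
#'
#' @param es an `edf_event_set` (only stage-labeled events are considered).
#' @param rec an `edf_recording_header` giving the span to cover.
#' @return list with `valid` (flag) and `problems` (character vector).
#' @export
validate_hypnogram <- function(es, rec) {
  t0 <- start_epoch_ms(rec)
  total_ms <- total_duration_s(rec) * 1000
  df <- as.data.frame(es)
  df <- df[df$label %in% .sleep_stages, , drop = FALSE]
  problems <- character(0)
  if (any(is.na(df$end_ms))) {
    problems <- c(problems, "stage events must be range events")
    df <- df[!is.na(df$end_ms), , drop = FALSE]
  }
  wrong_len <- df$end_ms - df$start_ms != .epoch_ms
  if (any(wrong_len)) {
    problems <- c(problems, sprintf("%d stage event(s) are not 30 s long",
                                    sum(wrong_len)))
  }
  misaligned <- (df$start_ms - t0) %% .epoch_ms != 0
  if (any(misaligned)) {
    problems <- c(problems, sprintf("%d stage event(s) not aligned to the epoch grid",
                                    sum(misaligned)))
  }
  k <- (df$start_ms - t0) %/% .epoch_ms
  if (anyDuplicated(k)) {
    problems <- c(problems, "overlapping stage events (duplicate epochs)")
  }
  n_epochs <- total_ms %/% .epoch_ms
  missing <- setdiff(seq_len(n_epochs) - 1, k)
  if (length(missing) > 0) {
    problems <- c(problems, sprintf("%d of %d epoch(s) unscored",
                                    length(missing), n_epochs))
  }
  list(valid = length(problems) == 0, problems = problems)
}

#' Default shortcut vocabulary for respiratory event labels
#'
#' The common apnea/hypopnea labels offered as marking shortcuts; a plain
#' character vector so deployments can supply their own list.
#' @export
apnea_labels <- function() {
  c("Obstructive Apnea", "Central Apnea", "Mixed Apnea", "Hypopnea", "RERA")
}
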