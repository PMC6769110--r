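# EDF/EDF+ header codec.
#
# Layout (byte-exact, all fields fixed-width space-padded ASCII):
#   static header, 256 bytes:
#     version(8) patient(80) recording(80) startdate(8) starttime(8)
#     header_bytes(8) reserved(44) num_records(8) record_duration(8)
#     num_signals(4)
#   dynamic header, 256 bytes per signal, field-by-field across signals:
#     label(16) transducer(80) dim(8) phys_min(8) phys_max(8) dig_min(8)
#     dig_max(8) prefilter(80) samples_per_record(8) reserved(32)
#   then num_records records of interleaved little-endian int16 samples.

.edf_static_fields <- c(
  version = 8L, patient_id = 80L, recording_id = 80L,
  start_date = 8L, start_time = 8L, header_bytes = 8L,
  reserved = 44L, num_records = 8L, record_duration = 8L,
  num_signals = 4L
)

.edf_signal_fields <- c(
  label = 16L, transducer = 80L, physical_dimension = 8L,
  physical_min = 8L, physical_max = 8L, digital_min = 8L,
  digital_max = 8L, prefiltering = 80L, samples_per_record = 8L,
  reserved = 32L
)

edf_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "edf_error", "error", "condition")))
}

# right-trim only: leading spaces can be significant in free-text fields
rtrim <- function(x) sub("[ ]+$", "", x)

edf_num <- function(s, field, integer = FALSE) {
  s <- trimws(s)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) || !nzchar(s)) {
    edf_error("edf_numeric_field_error",
              sprintf("field '%s' is not numeric: %s", field, dQuote(s)))
  }
  if (integer && v != round(v)) {
    edf_error("edf_numeric_field_error",
              sprintf("field '%s' must be an integer, got %s", field, s))
  }
  v
}

pad_field <- function(x, width, field = "field") {
  x <- as.character(x)
  if (grepl("[^\\x20-\\x7e]", x, perl = TRUE) || Encoding(x) == "UTF-8" && !validEnc(x)) {
    edf_error("edf_nonascii_error",
              sprintf("field '%s' contains non-printable or non-ASCII characters", field))
  }
  if (nchar(x, type = "bytes") > width) {
    edf_error("edf_field_overflow_error",
              sprintf("field '%s' exceeds %d characters: %s", field, width, dQuote(x)))
  }
  formatC(x, width = -width)
}

# shortest decimal representation fitting an 8-char EDF numeric field
format_edf_num <- function(v, width = 8L, field = "numeric field") {
  if (v == round(v) && abs(v) < 1e15) {
    s <- sprintf("%.0f", v)
  } else {
    s <- ""
    for (d in 15:1) {
      s <- formatC(signif(v, d), format = "fg", flag = "#", digits = d)
      s <- sub("\\.$", "", sub("0+$", "", s))
      if (nchar(s) <= width) break
    }
  }
  if (nchar(s) > width) {
    edf_error("edf_field_overflow_error",
              sprintf("value %s does not fit %d-char field '%s'", v, width, field))
  }
  s
}

# EDF+ two-digit-year clipping: yy >= 85 -> 19yy, else 20yy
edf_parse_date <- function(s) {
  m <- regmatches(s, regexec("^([0-9]{2})\\.([0-9]{2})\\.([0-9]{2})$", trimws(s)))[[1]]
  if (length(m) != 4L) {
    edf_error("edf_numeric_field_error", sprintf("malformed start date: %s", dQuote(s)))
  }
  d <- as.integer(m[2]); mo <- as.integer(m[3]); yy <- as.integer(m[4])
  y <- if (yy >= 85L) 1900L + yy else 2000L + yy
  as.Date(sprintf("%04d-%02d-%02d", y, mo, d))
}

edf_parse_time <- function(s) {
  m <- regmatches(s, regexec("^([0-9]{2})\\.([0-9]{2})\\.([0-9]{2})$", trimws(s)))[[1]]
  if (length(m) != 4L) {
    edf_error("edf_numeric_field_error", sprintf("malformed start time: %s", dQuote(s)))
  }
  as.integer(m[2]) * 3600L + as.integer(m[3]) * 60L + as.integer(m[4])
}

edf_format_date <- function(date) {
  format(as.Date(date), "%d.%m.%y")
}

edf_format_time <- function(sec) {
  sec <- as.integer(round(sec))
  sprintf("%02d.%02d.%02d", sec %/% 3600L, (sec %% 3600L) %/% 60L, sec %% 60L)
}

#' Construct a recording (static) header
#'
#' The static header carries file-level metadata.  Per the format, only the
#' `patient_id` field is intended to contain identifying information.
#'
#' @param patient_id,recording_id free-text identification fields (<= 80 chars).
#' @param start_date a `Date` (encoded dd.mm.yy in the file).
#' @param start_time seconds since midnight (encoded hh.mm.ss).
#' @param num_records number of data records (>= 0; the streaming sentinel -1
#'   is not supported).
#' @param record_duration_s duration of one record in seconds (> 0).
#' @param num_signals number of signals (>= 1).
#' @param version format version field, normally `"0"`.
#' @return an object of class `edf_recording_header`.
#' @export
recording_header <- function(patient_id = "X X X X", recording_id = "Startdate X X X X",
                             start_date = as.Date("2019-01-01"), start_time = 0L,
                             num_records, record_duration_s, num_signals,
                             version = "0") {
  rec <- structure(list(
    version = version,
    patient_id = patient_id,
    recording_id = recording_id,
    start_date = as.Date(start_date),
    start_time = as.integer(start_time),
    header_bytes = 256L * (as.integer(num_signals) + 1L),
    num_records = as.integer(num_records),
    record_duration_s = as.numeric(record_duration_s),
    num_signals = as.integer(num_signals)
  ), class = "edf_recording_header")
  validate_recording_header(rec)
  rec
}

validate_recording_header <- function(rec) {
  if (rec$num_records == -1L) {
    edf_error("edf_streaming_unsupported_error",
              "num_records == -1 (still-recording streaming file) is not supported")
  }
  if (rec$num_records < 0L) {
    edf_error("edf_header_consistency_error", "num_records must be >= 0")
  }
  if (!is.finite(rec$record_duration_s) || rec$record_duration_s <= 0) {
    edf_error("edf_header_consistency_error", "record_duration_s must be > 0")
  }
  if (rec$num_signals < 1L) {
    edf_error("edf_header_consistency_error", "num_signals must be >= 1")
  }
  if (rec$header_bytes != 256L * (rec$num_signals + 1L)) {
    edf_error("edf_header_consistency_error",
              sprintf("header_bytes (%d) != 256 x (num_signals + 1) (%d)",
                      rec$header_bytes, 256L * (rec$num_signals + 1L)))
  }
  invisible(rec)
}

#' Construct a signal (dynamic) header entry
#'
#' @param label 16-char signal label (e.g. `"EEG C4-A1"`).
#' @param samples_per_record samples of this signal in one data record.
#' @param physical_min,physical_max calibration range in physical units.
#' @param digital_min,digital_max calibration range in digital (int16) units.
#' @param physical_dimension unit text, e.g. `"uV"`.
#' @param transducer,prefiltering,reserved free-text metadata.
#' @return an object of class `edf_signal_header`.
#' @export
signal_header <- function(label, samples_per_record,
                          physical_min = -32768, physical_max = 32767,
                          digital_min = -32768L, digital_max = 32767L,
                          physical_dimension = "uV", transducer = "",
                          prefiltering = "", reserved = "") {
  sig <- structure(list(
    label = label,
    transducer = transducer,
    physical_dimension = physical_dimension,
    physical_min = as.numeric(physical_min),
    physical_max = as.numeric(physical_max),
    digital_min = as.integer(digital_min),
    digital_max = as.integer(digital_max),
    prefiltering = prefiltering,
    samples_per_record = as.integer(samples_per_record),
    reserved = reserved
  ), class = "edf_signal_header")
  validate_signal_header(sig)
  sig
}

validate_signal_header <- function(sig) {
  if (sig$digital_min >= sig$digital_max) {
    edf_error("edf_degenerate_range_error",
              sprintf("signal '%s': digital_min (%d) must be < digital_max (%d)",
                      rtrim(sig$label), sig$digital_min, sig$digital_max))
  }
  if (sig$digital_min < -32768L || sig$digital_max > 32767L) {
    edf_error("edf_degenerate_range_error",
              sprintf("signal '%s': digital range outside 16-bit signed bounds",
                      rtrim(sig$label)))
  }
  if (sig$physical_min == sig$physical_max) {
    edf_error("edf_degenerate_range_error",
              sprintf("signal '%s': physical_min == physical_max", rtrim(sig$label)))
  }
  if (sig$samples_per_record < 1L) {
    edf_error("edf_header_consistency_error",
              sprintf("signal '%s': samples_per_record must be >= 1", rtrim(sig$label)))
  }
  invisible(sig)
}

#' @export
print.edf_recording_header <- function(x, ...) {
  cat(sprintf("EDF recording: %d signal(s), %d record(s) x %g s = %g s\n",
              x$num_signals, x$num_records, x$record_duration_s,
              total_duration_s(x)))
  cat(sprintf("  start: %s %s  patient: \"%s\"\n", format(x$start_date),
              edf_format_time(x$start_time), x$patient_id))
  invisible(x)
}

#' Total recording duration in seconds
#' @param rec an `edf_recording_header`.
#' @export
total_duration_s <- function(rec) rec$num_records * rec$record_duration_s

#' Recording start as absolute epoch milliseconds (UTC)
#'
#' EDF carries no timezone; the start date/time is interpreted as UTC so that
#' timestamps are deterministic across machines.
#' @param rec an `edf_recording_header`.
#' @export
start_epoch_ms <- function(rec) {
  d <- as.numeric(as.POSIXct(as.character(rec$start_date), tz = "UTC"))
  (d + rec$start_time) * 1000
}

#' Exact sampling rate of a signal in Hz
#' @param sig an `edf_signal_header`.
#' @param rec the recording header (for the record duration).
#' @export
sampling_rate_hz <- function(sig, rec) sig$samples_per_record / rec$record_duration_s

#' Size of one data record in bytes (2 bytes per sample, all signals)
#' @param sigs list of `edf_signal_header`.
#' @export
record_size_bytes <- function(sigs) {
  2L * sum(vapply(sigs, function(s) s$samples_per_record, integer(1)))
}

#' Is a signal an EDF+ annotations channel?
#'
#' Detected by label; such channels are excluded from signal operations
#' (their byte stream is not interpreted as samples).
#' @param sig an `edf_signal_header`.
#' @export
is_annotation_channel <- function(sig) {
  identical(rtrim(sig$label), "EDF Annotations")
}

raw_field <- function(raw, from, width) {
  rawToChar(raw[from:(from + width - 1L)])
}

#' Parse EDF headers from raw bytes
#'
#' Decodes the 256-byte static header and the per-signal dynamic header.
#' Fixed-width ASCII fields are decoded with trailing-space trimming; the
#' original padded field text is retained (attribute `"padded"`) so that
#' [write_headers()] reproduces the input byte-for-byte.
#'
#' @param raw_bytes a raw vector holding at least the full header.
#' @return a list with elements `rec` (`edf_recording_header`) and
#'   `sigs` (list of `edf_signal_header`).
#' @seealso [write_headers()]
#' @export
parse_headers <- function(raw_bytes) {
  stopifnot(is.raw(raw_bytes))
  if (length(raw_bytes) < 256L) {
    edf_error("edf_truncated_error",
              sprintf("need at least 256 header bytes, got %d", length(raw_bytes)))
  }
  w <- .edf_static_fields
  off <- cumsum(c(1L, unname(w)))
  fields <- character(length(w))
  names(fields) <- names(w)
  for (i in seq_along(w)) fields[i] <- raw_field(raw_bytes, off[i], w[i])

  ns <- as.integer(edf_num(fields[["num_signals"]], "num_signals", integer = TRUE))
  if (ns < 1L) edf_error("edf_header_consistency_error", "num_signals must be >= 1")
  need <- 256L * (ns + 1L)
  if (length(raw_bytes) < need) {
    edf_error("edf_truncated_error",
              sprintf("header declares %d signals (%d bytes) but only %d bytes given",
                      ns, need, length(raw_bytes)))
  }
  hb <- as.integer(edf_num(fields[["header_bytes"]], "header_bytes", integer = TRUE))
  nr <- as.integer(edf_num(fields[["num_records"]], "num_records", integer = TRUE))
  if (nr == -1L) {
    edf_error("edf_streaming_unsupported_error",
              "num_records == -1 (still-recording streaming file) is not supported")
  }
  rd <- edf_num(fields[["record_duration"]], "record_duration")

  rec <- structure(list(
    version = rtrim(fields[["version"]]),
    patient_id = rtrim(fields[["patient_id"]]),
    recording_id = rtrim(fields[["recording_id"]]),
    start_date = edf_parse_date(fields[["start_date"]]),
    start_time = edf_parse_time(fields[["start_time"]]),
    header_bytes = hb,
    num_records = nr,
    record_duration_s = rd,
    num_signals = ns
  ), class = "edf_recording_header")
  attr(rec, "padded") <- fields
  if (hb != need) {
    edf_error("edf_header_consistency_error",
              sprintf("header_bytes field says %d, but 256 x (num_signals + 1) = %d",
                      hb, need))
  }
  validate_recording_header(rec)

  # dynamic header: each field stored contiguously for all signals
  sw <- .edf_signal_fields
  pos <- 257L
  sig_fields <- matrix("", nrow = ns, ncol = length(sw),
                       dimnames = list(NULL, names(sw)))
  for (j in seq_along(sw)) {
    for (i in seq_len(ns)) {
      sig_fields[i, j] <- raw_field(raw_bytes, pos, sw[j])
      pos <- pos + sw[j]
    }
  }
  sigs <- vector("list", ns)
  for (i in seq_len(ns)) {
    f <- sig_fields[i, ]
    sig <- structure(list(
      label = rtrim(f[["label"]]),
      transducer = rtrim(f[["transducer"]]),
      physical_dimension = rtrim(f[["physical_dimension"]]),
      physical_min = edf_num(f[["physical_min"]], "physical_min"),
      physical_max = edf_num(f[["physical_max"]], "physical_max"),
      digital_min = as.integer(edf_num(f[["digital_min"]], "digital_min", integer = TRUE)),
      digital_max = as.integer(edf_num(f[["digital_max"]], "digital_max", integer = TRUE)),
      prefiltering = rtrim(f[["prefiltering"]]),
      samples_per_record = as.integer(edf_num(f[["samples_per_record"]],
                                              "samples_per_record", integer = TRUE)),
      reserved = rtrim(f[["reserved"]])
    ), class = "edf_signal_header")
    attr(sig, "padded") <- f
    validate_signal_header(sig)
    sigs[[i]] <- sig
  }
  list(rec = rec, sigs = sigs)
}

format_static_fields <- function(rec) {
  c(version = pad_field(rec$version, 8L, "version"),
    patient_id = pad_field(rec$patient_id, 80L, "patient_id"),
    recording_id = pad_field(rec$recording_id, 80L, "recording_id"),
    start_date = pad_field(edf_format_date(rec$start_date), 8L, "start_date"),
    start_time = pad_field(edf_format_time(rec$start_time), 8L, "start_time"),
    header_bytes = pad_field(format_edf_num(rec$header_bytes, 8L), 8L, "header_bytes"),
    reserved = pad_field("", 44L, "reserved"),
    num_records = pad_field(format_edf_num(rec$num_records, 8L), 8L, "num_records"),
    record_duration = pad_field(format_edf_num(rec$record_duration_s, 8L,
                                               "record_duration"), 8L, "record_duration"),
    num_signals = pad_field(format_edf_num(rec$num_signals, 4L, "num_signals"),
                            4L, "num_signals"))
}

format_signal_fields <- function(sig) {
  c(label = pad_field(sig$label, 16L, "label"),
    transducer = pad_field(sig$transducer, 80L, "transducer"),
    physical_dimension = pad_field(sig$physical_dimension, 8L, "physical_dimension"),
    physical_min = pad_field(format_edf_num(sig$physical_min, 8L, "physical_min"),
                             8L, "physical_min"),
    physical_max = pad_field(format_edf_num(sig$physical_max, 8L, "physical_max"),
                             8L, "physical_max"),
    digital_min = pad_field(format_edf_num(sig$digital_min, 8L), 8L, "digital_min"),
    digital_max = pad_field(format_edf_num(sig$digital_max, 8L), 8L, "digital_max"),
    prefiltering = pad_field(sig$prefiltering, 80L, "prefiltering"),
    samples_per_record = pad_field(format_edf_num(sig$samples_per_record, 8L),
                                   8L, "samples_per_record"),
    reserved = pad_field(sig$reserved, 32L, "reserved"))
}

#' Encode EDF headers to raw bytes
#'
#' Inverse of [parse_headers()].  When headers came from a parse and were not
#' modified, the original padded field text is reused, so
#' `write_headers(parse_headers(b))` is byte-identical to `b` even for files
#' with unusual (but valid) field padding.
#'
#' @param rec an `edf_recording_header`.
#' @param sigs list of `edf_signal_header`, length `rec$num_signals`.
#' @return a raw vector of exactly `256 * (num_signals + 1)` bytes.
#' @export
write_headers <- function(rec, sigs) {
  validate_recording_header(rec)
  if (length(sigs) != rec$num_signals) {
    edf_error("edf_header_consistency_error",
              sprintf("got %d signal headers for num_signals = %d",
                      length(sigs), rec$num_signals))
  }
  fields <- attr(rec, "padded")
  if (is.null(fields)) fields <- format_static_fields(rec)
  sig_fields <- lapply(sigs, function(sig) {
    validate_signal_header(sig)
    f <- attr(sig, "padded")
    if (is.null(f)) f <- format_signal_fields(sig)
    f
  })
  sw <- .edf_signal_fields
  dyn <- character(0)
  for (j in names(sw)) {
    dyn <- c(dyn, vapply(sig_fields, function(f) f[[j]], character(1)))
  }
  out <- charToRaw(paste0(paste(fields, collapse = ""), paste(dyn, collapse = "")))
  stopifnot(length(out) == 256L * (rec$num_signals + 1L))
  out
}

#' Modify a header field, keeping the padded byte representation in sync
#'
#' Headers parsed from a file keep their original padded text so re-encoding
#' is byte-exact; any modification must go through this setter so the padded
#' copy of the changed field is regenerated (all other fields keep their
#' original bytes).
#'
#' @param hdr an `edf_recording_header` or `edf_signal_header`.
#' @param field field name, e.g. `"patient_id"`.
#' @param value new value.
#' @export
edf_set_field <- function(hdr, field, value) {
  hdr[[field]] <- value
  padded <- attr(hdr, "padded")
  if (!is.null(padded)) {
    fresh <- if (inherits(hdr, "edf_recording_header")) {
      format_static_fields(hdr)
    } else {
      format_signal_fields(hdr)
    }
    key <- if (field == "record_duration_s") "record_duration" else field
    padded[[key]] <- fresh[[key]]
    attr(hdr, "padded") <- padded
  }
  hdr
}

#' Digital to physical calibration
#'
#' EDF stores samples as 16-bit integers; each signal header defines an
#' affine map between the digital and physical ranges:
#' `p = physical_min + (d - digital_min) * (physical_max - physical_min) /
#' (digital_max - digital_min)`.  Exact at both calibration endpoints.
#'
#' @param d digital value(s).
#' @param sig an `edf_signal_header`.
#' @return physical value(s) in `sig$physical_dimension` units.
#' @export
digital_to_physical <- function(d, sig) {
  if (sig$digital_min >= sig$digital_max) {
    edf_error("edf_degenerate_range_error", "degenerate digital range")
  }
  sig$physical_min + (d - sig$digital_min) *
    (sig$physical_max - sig$physical_min) / (sig$digital_max - sig$digital_min)
}

#' Physical to digital calibration (inverse affine map, not rounded)
#' @inheritParams digital_to_physical
#' @param p physical value(s).
#' @export
physical_to_digital <- function(p, sig) {
  if (sig$digital_min >= sig$digital_max) {
    edf_error("edf_degenerate_range_error", "degenerate digital range")
  }
  sig$digital_min + (p - sig$physical_min) *
    (sig$digital_max - sig$digital_min) / (sig$physical_max - sig$physical_min)
}
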