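# Deterministic synthetic EDF generator.
#
# Every test runs against files generated here, with exact known digital
# samples as ground truth -- no downloaded recordings needed.  The same
# seed always yields a byte-identical file.

#' Describe one synthetic channel
#'
#' @param label channel label (may be a vendor variant for harmonization
#'   tests).
#' @param fs sampling rate in Hz; `fs * record_duration_s` must be integral.
#' @param waveform one of `"sine"`, `"square"`, `"gaussian-noise"`,
#'   `"ramp"`, `"constant"`.
#' @param amplitude physical amplitude (for `"constant"`: the value itself).
#' @param physical_min,physical_max,digital_min,digital_max calibration
#'   ranges; defaults map digital units 1:1 to physical units.
#' @param wave_hz oscillation frequency for sine/square.
#' @param physical_dimension unit text.
#' @export
fixture_channel <- function(label, fs, waveform = "gaussian-noise",
                            amplitude = 100,
                            physical_min = -32768, physical_max = 32767,
                            digital_min = -32768L, digital_max = 32767L,
                            wave_hz = 1, physical_dimension = "uV") {
  waveform <- match.arg(waveform,
                        c("sine", "square", "gaussian-noise", "ramp", "constant"))
  list(label = label, fs = fs, waveform = waveform, amplitude = amplitude,
       physical_min = physical_min, physical_max = physical_max,
       digital_min = as.integer(digital_min), digital_max = as.integer(digital_max),
       wave_hz = wave_hz, physical_dimension = physical_dimension)
}

#' Describe a synthetic EDF recording
#'
#' @param seed RNG seed; all randomness (noise channels) derives from it.
#' @param duration_s total duration; must be a multiple of
#'   `record_duration_s`.
#' @param record_duration_s record length in seconds.
#' @param channels list of [fixture_channel()] descriptions.
#' @param patient_id,recording_id header identification text.
#' @param start_datetime recording start (`POSIXct`, interpreted as UTC).
#' @export
fixture_spec <- function(seed = 1L, duration_s = 10, record_duration_s = 1,
                         channels = list(
                           fixture_channel("EEG C4-A1", 100, "sine", amplitude = 50),
                           fixture_channel("Resp nasal", 4, "ramp", amplitude = 40)
                         ),
                         patient_id = "X X 01-JAN-1985 X",
                         recording_id = "Startdate 01-JAN-2019 X X X",
                         start_datetime = as.POSIXct("2019-01-01 00:00:00", tz = "UTC")) {
  nrec <- duration_s / record_duration_s
  if (abs(nrec - round(nrec)) > 1e-9) {
    edf_error("edf_fixture_error", "duration_s must be a multiple of record_duration_s")
  }
  for (ch in channels) {
    spr <- ch$fs * record_duration_s
    if (abs(spr - round(spr)) > 1e-9 || spr < 1) {
      edf_error("edf_fixture_error",
                sprintf("channel '%s': fs x record_duration_s = %g is not a positive integer",
                        ch$label, spr))
    }
  }
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 record_duration_s = record_duration_s, channels = channels,
                 patient_id = patient_id, recording_id = recording_id,
                 start_datetime = start_datetime),
            class = "edf_fixture_spec")
}

fixture_waveform <- function(ch, n, spr, record_duration_s) {
  t <- (seq_len(n) - 1) / ch$fs
  phys <- switch(ch$waveform,
    sine = ch$amplitude * sin(2 * pi * ch$wave_hz * t),
    square = ch$amplitude * ifelse(sin(2 * pi * ch$wave_hz * t) >= 0, 1, -1),
    `gaussian-noise` = stats::rnorm(n, 0, ch$amplitude),
    # ramp resets each record: strictly increasing within a record span
    ramp = {
      within <- (seq_len(n) - 1) %% spr
      -ch$amplitude + (2 * ch$amplitude) * within / max(spr - 1, 1)
    },
    constant = rep(ch$amplitude, n)
  )
  d <- round(physical_to_digital(phys, ch))
  if (any(d < ch$digital_min | d > ch$digital_max)) {
    edf_error("edf_fixture_error",
              sprintf("channel '%s': amplitude exceeds the digital range", ch$label))
  }
  as.integer(d)
}

#' Generate a synthetic EDF file with known ground truth
#'
#' Writes a structurally valid EDF file and returns the exact digital
#' samples per channel for oracle comparisons.  Same spec (same seed) twice
#' gives byte-identical files.  A JSON sidecar (`<path>.json`) records the
#' spec and per-channel digital samples.
#'
#' @param spec an [fixture_spec()].
#' @param path output file path.
#' @param sidecar write the JSON ground-truth sidecar?
#' @return invisibly, a list with `rec`, `sigs`, `digital` (list of integer
#'   vectors), `path`.
#' @export
generate_edf <- function(spec, path, sidecar = FALSE) {
  nrec <- as.integer(round(spec$duration_s / spec$record_duration_s))
  ns <- length(spec$channels)
  start <- as.POSIXlt(spec$start_datetime, tz = "UTC")
  rec <- recording_header(
    patient_id = spec$patient_id, recording_id = spec$recording_id,
    start_date = as.Date(start), start_time = start$hour * 3600L +
      start$min * 60L + as.integer(start$sec),
    num_records = nrec, record_duration_s = spec$record_duration_s,
    num_signals = ns
  )
  sigs <- lapply(spec$channels, function(ch) {
    signal_header(ch$label, as.integer(round(ch$fs * spec$record_duration_s)),
                  physical_min = ch$physical_min, physical_max = ch$physical_max,
                  digital_min = ch$digital_min, digital_max = ch$digital_max,
                  physical_dimension = ch$physical_dimension)
  })
  digital <- withr::with_seed(spec$seed, {
    lapply(seq_len(ns), function(i) {
      ch <- spec$channels[[i]]
      spr <- sigs[[i]]$samples_per_record
      fixture_waveform(ch, nrec * spr, spr, spec$record_duration_s)
    })
  })
  # interleave into records: per record, each channel's samples appended
  spr <- vapply(sigs, function(s) s$samples_per_record, integer(1))
  mats <- lapply(seq_len(ns), function(i) matrix(digital[[i]], nrow = spr[i]))
  body <- integer(nrec * sum(spr))
  pos <- 0L
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      body[pos + seq_len(spr[i])] <- mats[[i]][, r]
      pos <- pos + spr[i]
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(write_headers(rec, sigs), con)
  writeBin(body, con, size = 2L, endian = "little")
  if (sidecar) {
    jsonlite::write_json(
      list(seed = spec$seed, duration_s = spec$duration_s,
           record_duration_s = spec$record_duration_s,
           labels = vapply(spec$channels, `[[`, character(1), "label"),
           digital = digital),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(rec = rec, sigs = sigs, digital = digital, path = path))
}

#' A PSG-like fixture spec: 16 mixed-rate channels with vendor labels
#'
#' Emulates the structure of a routine polysomnography (at least 16
#' signals, mixed sampling rates: high-rate EEG/EOG/EMG/ECG, low-rate
#' airflow/effort/saturation), with channel labels drawn from the variants
#' in the bundled harmonization seed table so every label is harmonizable.
#' Kept short (default 30 s) so the file stays well under a few MB.
#'
#' @param seed RNG seed.
#' @param duration_s total duration in seconds.
#' @return an [fixture_spec()].
#' @export
generate_psg_like <- function(seed = 1L, duration_s = 30) {
  eeg <- function(lab) fixture_channel(lab, 250, "gaussian-noise", amplitude = 30,
                                       physical_min = -200, physical_max = 200,
                                       digital_min = -2048L, digital_max = 2047L)
  channels <- list(
    eeg("EEG C4-A1"), eeg("EEGC3-A2"), eeg("EEG F4-A1"), eeg("F3-A2"),
    eeg("EEG O2-A1"), eeg("O1-A2"),
    fixture_channel("EOG LEFT", 250, "sine", amplitude = 80, wave_hz = 0.3,
                    physical_min = -500, physical_max = 500,
                    digital_min = -2048L, digital_max = 2047L),
    fixture_channel("EOG RIGHT", 250, "sine", amplitude = 80, wave_hz = 0.25,
                    physical_min = -500, physical_max = 500,
                    digital_min = -2048L, digital_max = 2047L),
    fixture_channel("CHIN1", 250, "gaussian-noise", amplitude = 10,
                    physical_min = -100, physical_max = 100,
                    digital_min = -2048L, digital_max = 2047L),
    fixture_channel("LEGBEINLI", 250, "gaussian-noise", amplitude = 10,
                    physical_min = -100, physical_max = 100,
                    digital_min = -2048L, digital_max = 2047L),
    fixture_channel("LEGBEINRE", 250, "gaussian-noise", amplitude = 10,
                    physical_min = -100, physical_max = 100,
                    digital_min = -2048L, digital_max = 2047L),
    fixture_channel("EKG II", 250, "square", amplitude = 1, wave_hz = 1.2,
                    physical_min = -5, physical_max = 5,
                    digital_min = -2048L, digital_max = 2047L,
                    physical_dimension = "mV"),
    fixture_channel("AIRFLOW", 25, "sine", amplitude = 40, wave_hz = 0.25,
                    physical_min = -100, physical_max = 100,
                    digital_min = -2048L, digital_max = 2047L),
    fixture_channel("THOR RES", 25, "sine", amplitude = 30, wave_hz = 0.25,
                    physical_min = -100, physical_max = 100,
                    digital_min = -2048L, digital_max = 2047L),
    fixture_channel("ABDO RES", 25, "sine", amplitude = 30, wave_hz = 0.22,
                    physical_min = -100, physical_max = 100,
                    digital_min = -2048L, digital_max = 2047L),
    fixture_channel("SPO2", 1, "constant", amplitude = 96,
                    physical_min = 0, physical_max = 100,
                    digital_min = 0L, digital_max = 100L,
                    physical_dimension = "%")
  )
  fixture_spec(seed = seed, duration_s = duration_s, record_duration_s = 1,
               channels = channels)
}
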