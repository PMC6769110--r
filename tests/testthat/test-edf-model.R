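# Header codec and calibration.

# independent fixed-offset assembly of a 2-signal static+dynamic header,
# built field by field from the format's byte layout (not via write_headers)
hand_built_header <- function() {
  pad <- function(x, w) formatC(x, width = -w)
  static <- paste0(
    pad("0", 8), pad("X Y 01-JAN-1990 Pat", 80), pad("Startdate 01-JAN-2019 X", 80),
    pad("01.01.19", 8), pad("00.00.00", 8), pad("768", 8), pad("", 44),
    pad("10", 8), pad("1", 8), pad("2", 4))
  dynamic <- paste0(
    pad("EEG C4-A1", 16), pad("Resp nasal", 16),      # labels
    pad("", 80), pad("", 80),                          # transducers
    pad("uV", 8), pad("L/s", 8),                       # dims
    pad("-200", 8), pad("-40", 8),                     # phys min
    pad("200", 8), pad("40", 8),                       # phys max
    pad("-2048", 8), pad("-512", 8),                   # dig min
    pad("2047", 8), pad("511", 8),                     # dig max
    pad("", 80), pad("", 80),                          # prefilter
    pad("100", 8), pad("4", 8),                        # samples/record
    pad("", 32), pad("", 32))                          # reserved
  charToRaw(paste0(static, dynamic))
}

test_that("hand-assembled header parses to the expected fields", {
  b <- hand_built_header()
  expect_length(b, 768)
  h <- parse_headers(b)
  expect_equal(h$rec$num_signals, 2L)
  expect_equal(h$rec$header_bytes, 768L)
  expect_equal(h$rec$num_records, 10L)
  expect_equal(h$rec$record_duration_s, 1)
  expect_equal(total_duration_s(h$rec), 10)
  expect_equal(h$rec$patient_id, "X Y 01-JAN-1990 Pat")
  expect_equal(h$rec$start_date, as.Date("2019-01-01"))
  expect_equal(h$sigs[[1]]$label, "EEG C4-A1")
  expect_equal(h$sigs[[1]]$samples_per_record, 100L)
  expect_equal(h$sigs[[2]]$physical_max, 40)
  expect_equal(sampling_rate_hz(h$sigs[[1]], h$rec), 100)
  # patient field occupies bytes 8..87 (0-based), space padded
  expect_equal(rawToChar(b[9:88]), formatC("X Y 01-JAN-1990 Pat", width = -80))
})

test_that("write(parse(b)) is byte-identical, with and without edits", {
  b <- hand_built_header()
  h <- parse_headers(b)
  expect_identical(write_headers(h$rec, h$sigs), b)
  # an edited field re-encodes in place; all other bytes stay put
  rec2 <- edf_set_field(h$rec, "patient_id", "ABC123")
  b2 <- write_headers(rec2, h$sigs)
  expect_identical(b2[-(9:88)], b[-(9:88)])
  expect_equal(rawToChar(b2[9:88]), formatC("ABC123", width = -80))
})

test_that("header error paths raise distinct named conditions", {
  b <- hand_built_header()
  expect_error(parse_headers(b[1:100]), class = "edf_truncated_error")
  expect_error(parse_headers(b[1:500]), class = "edf_truncated_error")
  bad <- b
  bad[185:192] <- charToRaw(formatC("512", width = -8))  # header_bytes field
  expect_error(parse_headers(bad), class = "edf_header_consistency_error")
  bad <- b
  bad[237:244] <- charToRaw(formatC("-1", width = -8))   # num_records field
  expect_error(parse_headers(bad), class = "edf_streaming_unsupported_error")
  bad <- b
  bad[245:252] <- charToRaw(formatC("abc", width = -8))  # record_duration field
  expect_error(parse_headers(bad), class = "edf_numeric_field_error")
  expect_error(
    recording_header(patient_id = strrep("x", 81), num_records = 1,
                     record_duration_s = 1, num_signals = 1) |>
      write_headers(list(signal_header("A", 1))),
    class = "edf_field_overflow_error")
  expect_error(
    write_headers(recording_header(patient_id = "café", num_records = 1,
                                   record_duration_s = 1, num_signals = 1),
                  list(signal_header("A", 1))),
    class = "edf_nonascii_error")
})

test_that("two-digit years follow the 1985 clipping convention", {
  d <- function(s) {
    b <- hand_built_header()
    b[169:176] <- charToRaw(s)
    parse_headers(b)$rec$start_date
  }
  expect_equal(d("01.01.85"), as.Date("1985-01-01"))
  expect_equal(d("31.12.99"), as.Date("1999-12-31"))
  expect_equal(d("01.01.00"), as.Date("2000-01-01"))
  expect_equal(d("02.03.84"), as.Date("2084-03-02"))
})

test_that("digital_to_physical is the documented affine map", {
  sig <- signal_header("T", 10, physical_min = -200, physical_max = 200,
                       digital_min = -2048L, digital_max = 2047L)
  expect_equal(digital_to_physical(sig$digital_min, sig), sig$physical_min)
  expect_equal(digital_to_physical(sig$digital_max, sig), sig$physical_max)
  # independent evaluation of the affine map at d = 0
  expect_equal(digital_to_physical(0L, sig), 2048 * 400 / 4095 - 200)
  expect_equal(digital_to_physical(0L, sig), 0.04884, tolerance = 1e-4)
  # affinity: f(a) + f(b) == 2 f((a+b)/2) for even a+b
  withr::with_seed(7, {
    a <- sample(-2048:2047, 200, replace = TRUE)
    b <- a + 2 * sample(-100:100, 200, replace = TRUE)
    expect_equal(digital_to_physical(a, sig) + digital_to_physical(b, sig),
                 2 * digital_to_physical((a + b) / 2, sig))
  })
  degenerate <- sig
  degenerate$digital_max <- degenerate$digital_min
  expect_error(digital_to_physical(0, degenerate),
               class = "edf_degenerate_range_error")
  # round trip with the inverse map
  expect_equal(physical_to_digital(digital_to_physical(-100L, sig), sig), -100)
})

test_that("codec round-trips 1000 randomized header specs byte-identically", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      ns <- sample(1:5, 1)
      rec <- recording_header(
        patient_id = paste(sample(c(LETTERS, letters, 0:9, " ", "-"),
                                  sample(0:60, 1), replace = TRUE), collapse = ""),
        recording_id = paste(sample(c(LETTERS, " "), sample(0:40, 1),
                                    replace = TRUE), collapse = ""),
        start_date = as.Date("1985-01-01") + sample(0:20000, 1),
        start_time = sample(0:86399, 1),
        num_records = sample(0:5000, 1),
        record_duration_s = sample(c(0.25, 0.5, 1, 2, 30), 1),
        num_signals = ns)
      sigs <- lapply(seq_len(ns), function(j) {
        dr <- sort(sample(-32768:32767, 2))
        signal_header(paste0("S", j), sample(1:500, 1),
                      physical_min = round(stats::runif(1, -5000, 0), 3),
                      physical_max = round(stats::runif(1, 1, 5000), 3),
                      digital_min = dr[1], digital_max = dr[2])
      })
      b1 <- write_headers(rec, sigs)
      h <- parse_headers(b1)
      b2 <- write_headers(h$rec, h$sigs)
      if (!identical(b1, b2)) {
        fail(sprintf("round trip differs for seed iteration %d", i))
        break
      }
    }
    succeed()
  })
})

test_that("EDF Annotations channels are flagged and excluded from signal ops", {
  spec <- fixture_spec(seed = 3, duration_s = 4, record_duration_s = 1,
                       channels = list(
                         fixture_channel("EEG C4-A1", 10, "sine", amplitude = 50),
                         fixture_channel("EDF Annotations", 2, "constant",
                                         amplitude = 0)))
  f <- withr::local_tempfile(fileext = ".edf")
  generate_edf(spec, f)
  x <- open_edf(f)
  expect_true(is_annotation_channel(x$sigs[[2]]))
  expect_false(is_annotation_channel(x$sigs[[1]]))
  s <- read_segment(x, c(0, 4))
  expect_length(s, 1)
  expect_equal(s[[1]]$channel_index, 1L)
})
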