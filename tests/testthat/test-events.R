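# Event model and JSON interchange.

test_that("literal export matches the keyed-object format", {
  es <- event_set(1546300800000, "Obstructive Apnea")
  expect_equal(export_events(es), "{\"1546300800000\":\"Obstructive Apnea\"}")
  expect_equal(export_events(event_set()), "{}")
  # keys come out in ascending numeric order
  es <- event_set(c(2000, 500, 1500), c("b", "a", "c"))
  keys <- names(jsonlite::fromJSON(export_events(es), simplifyVector = FALSE))
  expect_equal(keys, c("500", "1500", "2000"))
})

test_that("round trips are exact; the literal dialect drops range fields only", {
  withr::with_seed(23, {
    for (i in 1:100) {
      n <- sample(0:20, 1)
      start <- sort(sample(1e12 + 0:1e6, n)) * 1
      has_end <- sample(c(TRUE, FALSE), n, replace = TRUE)
      es <- event_set(start,
                      label = sample(apnea_labels(), n, replace = TRUE),
                      end_ms = ifelse(has_end, start + sample(1000:30000, pmax(n, 1))[seq_len(n)], NA),
                      channel = sample(c(NA, "EEG C4-A1"), n, replace = TRUE))
      back <- import_events(export_events(es, dialect = "extended"))
      expect_equal(back$start_ms, es$start_ms)
      expect_equal(back$end_ms, es$end_ms)
      expect_equal(back$label, es$label)
      expect_equal(back$channel, es$channel)
      lit <- import_events(export_events(es, dialect = "literal"))
      expect_equal(lit$start_ms, es$start_ms)
      expect_equal(lit$label, es$label)
      expect_true(all(is.na(lit$end_ms)))      # documented lossiness
      expect_true(all(is.na(lit$channel)))
    }
  })
})

test_that("duplicate start timestamps are nudged with a warning on export", {
  es <- event_set(c(1000, 1000), c("A", "B"))
  expect_warning(txt <- export_events(es), "nudged")
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_setequal(names(obj), c("1000", "1001"))
})

test_that("malformed JSON and bad keys raise named errors", {
  expect_error(import_events("{not json"), class = "edf_event_json_error")
  expect_error(import_events("{\"abc\": \"X\"}"), class = "edf_event_json_error")
  expect_error(import_events("[1,2,3]"), class = "edf_event_json_error")
  expect_error(import_events("{\"1000\": 42}"), class = "edf_event_json_error")
})

test_that("edit operations keep order and obey their contracts", {
  es <- event_set(c(1000, 5000), c("Hypopnea", "Central Apnea"),
                  end_ms = c(3000, 9000))
  # move preserves duration
  moved <- move_event(es, 1, 30000)
  i <- which(moved$label == "Hypopnea")
  expect_equal(moved$start_ms[i], 31000)
  expect_equal(moved$end_ms[i] - moved$start_ms[i], 2000)
  expect_equal(moved$start_ms, sort(moved$start_ms))
  # resize keeps the fixed bound; inverted ranges rejected
  resized <- resize_event(es, 1, new_end_ms = 2000)
  expect_equal(resized$start_ms[1], 1000)
  expect_equal(resized$end_ms[1], 2000)
  expect_error(resize_event(es, 1, new_end_ms = 1000),
               class = "edf_event_range_error")
  expect_error(remove_event(es, 99), class = "edf_unknown_event_error")
  # add n then remove all -> empty
  withr::with_seed(3, {
    acc <- event_set()
    for (k in 1:100) {
      acc <- add_event(acc, sample(1e9, 1), sample(apnea_labels(), 1))
    }
    expect_equal(nrow(acc), 100)
    for (k in 100:1) acc <- remove_event(acc, sample(k, 1))
    expect_equal(nrow(acc), 0)
  })
})

test_that("ingesting external events merges, dedups, keeps sources", {
  es <- event_set(c(1000, 2000), c("A", "B"), end_ms = c(1500, 2500))
  txt <- export_events(es, dialect = "extended")
  # merging a set with itself is a no-op (modulo the source tag)
  merged <- ingest_external_events(txt, es)
  expect_equal(nrow(merged), 2)
  # disjoint sets: sorted union
  other <- event_set(c(500, 3000), c("C", "D"))
  merged <- ingest_external_events(export_events(other, "extended"), es,
                                   source = "xnat")
  expect_equal(nrow(merged), 4)
  expect_equal(merged$start_ms, c(500, 1000, 2000, 3000))
  expect_equal(merged$source[merged$label %in% c("C", "D")], c("xnat", "xnat"))
  # overlapping but non-identical events are both kept
  near <- event_set(1000, "A", end_ms = 1400)    # same start+label, other end
  merged <- ingest_external_events(export_events(near, "extended"), es)
  expect_equal(nrow(merged), 3)
})

test_that("hypnogram validation checks stages, alignment and coverage", {
  rec <- recording_header(num_records = 120, record_duration_s = 1,
                          num_signals = 1)           # 120 s = 4 epochs
  t0 <- start_epoch_ms(rec)
  full <- event_set(t0 + (0:3) * 30000, c("W", "N1", "N2", "R"),
                    end_ms = t0 + (1:4) * 30000)
  v <- validate_hypnogram(full, rec)
  expect_true(v$valid)
  # missing epoch
  v <- validate_hypnogram(remove_event(full, 2), rec)
  expect_false(v$valid)
  expect_match(paste(v$problems, collapse = " "), "unscored")
  # misaligned stage
  v <- validate_hypnogram(move_event(full, 2, 1000), rec)
  expect_false(v$valid)
  # wrong length
  v <- validate_hypnogram(resize_event(full, 1, new_end_ms = t0 + 20000), rec)
  expect_false(v$valid)
  # non-stage labels are ignored by the validator
  with_apnea <- add_event(full, t0 + 45000, "Obstructive Apnea",
                          end_ms = t0 + 58000)
  expect_true(validate_hypnogram(with_apnea, rec)$valid)
})
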