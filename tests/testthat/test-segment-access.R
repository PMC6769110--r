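# Time-range -> byte-range mapping, lazy reads, strategies, prefetch cache.

make_two_signal_recording <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  spec <- fixture_spec(seed = 11, duration_s = 10, record_duration_s = 1,
                       channels = list(
                         fixture_channel("EEG C4-A1", 100, "gaussian-noise",
                                         amplitude = 40, physical_min = -200,
                                         physical_max = 200, digital_min = -2048L,
                                         digital_max = 2047L),
                         fixture_channel("Resp nasal", 4, "ramp", amplitude = 30,
                                         physical_min = -100, physical_max = 100,
                                         digital_min = -2048L, digital_max = 2047L)))
  path <- file.path(dir, "two.edf")
  gt <- generate_edf(spec, path)
  list(path = path, gt = gt)
}

test_that("time_range_to_byte_range returns the smallest covering record span", {
  r <- make_two_signal_recording()
  x <- open_edf(r$path)
  # brute-force oracle: enumerate each record's byte interval and collect
  # the ones intersecting the time range
  oracle <- function(start_s, end_s) {
    rs <- 2 * (100 + 4)
    recs <- Filter(function(k) (k + 1) > start_s && k < end_s, 0:9)
    c(offset = 768 + min(recs) * rs, length = length(recs) * rs)
  }
  br <- time_range_to_byte_range(time_range(2, 5), x$rec, x$sigs)
  expect_equal(br$offset, 768 + 2 * 208)   # 1184
  expect_equal(br$length, 3 * 208)         # 624
  expect_equal(c(offset = br$offset, length = br$length), oracle(2, 5))
  # whole file
  br <- time_range_to_byte_range(time_range(0, 10), x$rec, x$sigs)
  expect_equal(br$offset, x$rec$header_bytes)
  expect_equal(br$length, 10 * 208)
  # sub-record range maps to exactly record 0
  br <- time_range_to_byte_range(time_range(0.5, 0.6), x$rec, x$sigs)
  expect_equal(br$first_record, 0)
  expect_equal(br$last_record, 0)
  # randomized agreement with the brute-force oracle
  withr::with_seed(5, {
    for (i in 1:50) {
      s <- round(stats::runif(1, 0, 9.5), 3)
      e <- round(stats::runif(1, s + 0.01, 10), 3)
      br <- time_range_to_byte_range(time_range(s, e), x$rec, x$sigs)
      expect_equal(c(offset = br$offset, length = br$length), oracle(s, e))
    }
  })
  expect_error(time_range_to_byte_range(time_range(12, 14), x$rec, x$sigs),
               class = "edf_empty_range_error")
  expect_error(time_range(5, 5), class = "edf_empty_range_error")
})

test_that("read_segment equals the ground truth and slices of a whole-file parse", {
  r <- make_two_signal_recording()
  x <- open_edf(r$path)
  whole <- read_segment(x, c(0, 10))
  for (i in 1:2) {
    expect_identical(whole[[i]]$min_values, ground_truth_physical(r$gt, i))
    expect_identical(whole[[i]]$min_values, whole[[i]]$max_values)
    # timestamps: absolute epoch ms from the start datetime
    t0 <- start_epoch_ms(x$rec)
    fs <- sampling_rate_hz(x$sigs[[i]], x$rec)
    expect_equal(whole[[i]]$timestamps_ms,
                 t0 + (seq_along(r$gt$digital[[i]]) - 1) / fs * 1000)
  }
  # partial read == slice of the whole-file parse (whole parse is the oracle)
  part <- read_segment(x, c(3.25, 7.75))
  for (i in 1:2) {
    keep <- whole[[i]]$timestamps_ms >= start_epoch_ms(x$rec) + 3250 &
      whole[[i]]$timestamps_ms < start_epoch_ms(x$rec) + 7750
    expect_identical(part[[i]]$min_values, whole[[i]]$min_values[keep])
    expect_identical(part[[i]]$timestamps_ms, whole[[i]]$timestamps_ms[keep])
  }
  # clipping and empty ranges
  clipped <- read_segment(x, c(8, 15))
  expect_equal(length(clipped[[2]]$min_values), 2 * 4)
  expect_error(read_segment(x, c(11, 15)), class = "edf_empty_range_error")
})

test_that("local strategy reads exact byte windows", {
  r <- make_two_signal_recording()
  s <- local_file_strategy(r$path)
  expect_identical(rawToChar(read_bytes(s, 0, 8)), formatC("0", width = -8))
  expect_equal(s$size(), file.size(r$path))
  b <- readBin(r$path, "raw", file.size(r$path))
  expect_identical(read_bytes(s, 100, 50), b[101:150])
  # concatenation property
  expect_identical(c(read_bytes(s, 40, 25), read_bytes(s, 65, 35)),
                   read_bytes(s, 40, 60))
  expect_error(local_file_strategy(file.path(tempdir(), "nope.edf")),
               class = "edf_missing_file_error")
})

test_that("http strategy is byte-identical to the local strategy", {
  dir <- withr::local_tempdir()
  r <- make_two_signal_recording(dir)
  srv <- local_fixture_server(dir)
  loc <- local_file_strategy(r$path)
  rem <- http_range_strategy(srv$url("two.edf"))
  expect_equal(rem$size(), loc$size())
  n <- loc$size()
  withr::with_seed(13, {
    for (i in 1:100) {
      o <- sample(0:(n - 2), 1)
      l <- sample(1:min(400, n - o), 1)
      expect_identical(read_bytes(rem, o, l), read_bytes(loc, o, l))
    }
  })
  # a whole recording opened remotely behaves like the local one
  xr <- open_edf(srv$url("two.edf"))
  xl <- open_edf(r$path)
  sr <- read_segment(xr, c(2.5, 6.5))
  sl <- read_segment(xl, c(2.5, 6.5))
  expect_identical(sr[[1]]$min_values, sl[[1]]$min_values)
})

test_that("a server without range support raises a capability error", {
  dir <- withr::local_tempdir()
  r <- make_two_signal_recording(dir)
  srv <- local_fixture_server(dir, ranges = FALSE)
  rem <- http_range_strategy(srv$url("two.edf"))
  expect_error(read_bytes(rem, 0, 8), class = "edf_http_range_unsupported_error")
})

test_that("ensure_window covers the +/-2W span, evicts, and is idempotent", {
  spec <- fixture_spec(seed = 21, duration_s = 700, record_duration_s = 1,
                       channels = list(fixture_channel("EEG C4-A1", 10,
                                                       "gaussian-noise",
                                                       amplitude = 30,
                                                       physical_min = -200,
                                                       physical_max = 200,
                                                       digital_min = -2048L,
                                                       digital_max = 2047L)))
  f <- withr::local_tempfile(fileext = ".edf")
  generate_edf(spec, f)
  cs <- counting_strategy(local_file_strategy(f))
  x <- open_edf(cs)
  cache <- segment_cache(x)

  ensure_window(cache, c(60, 90))          # W = 30
  cov <- cache_coverage(cache)
  expect_equal(c(cov$start_s, cov$end_s), c(0, 150))
  n0 <- cs$n_reads()
  ensure_window(cache, c(60, 90))          # repeated call: no new reads
  expect_equal(cs$n_reads(), n0)
  expect_equal(c(cache_coverage(cache)$start_s, cache_coverage(cache)$end_s),
               c(0, 150))

  ensure_window(cache, c(600, 630))        # jump: old span evicted
  cov <- cache_coverage(cache)
  expect_equal(c(cov$start_s, cov$end_s), c(540, 690))
  expect_null(get_cached(cache, c(0, 30)))

  ensure_window(cache, c(0, 30))           # left boundary clip
  cov <- cache_coverage(cache)
  expect_equal(c(cov$start_s, cov$end_s), c(0, 90))

  # scrolling one viewport right costs at most one read per side
  cs$reset()
  ensure_window(cache, c(30, 60))
  expect_lte(cs$n_reads(), 2)
  cov <- cache_coverage(cache)
  expect_equal(c(cov$start_s, cov$end_s), c(0, 120))
})

test_that("reads served from the cache are byte-identical and strategy-free", {
  spec <- generate_psg_like(seed = 4, duration_s = 60)
  f <- withr::local_tempfile(fileext = ".edf")
  generate_edf(spec, f)
  cs <- counting_strategy(local_file_strategy(f))
  x <- open_edf(cs)
  cache <- segment_cache(x)
  ensure_window(cache, c(20, 30))
  baseline <- read_segment(x, c(22, 28))            # uncached
  n0 <- cs$n_reads()
  cached <- read_segment(x, c(22, 28), cache = cache)
  expect_equal(cs$n_reads(), n0)                    # no strategy read
  for (i in seq_along(baseline)) {
    expect_identical(cached[[i]]$min_values, baseline[[i]]$min_values)
    expect_identical(cached[[i]]$timestamps_ms, baseline[[i]]$timestamps_ms)
  }
  # a miss outside the cached span ([0, 50] here) falls back to the strategy
  out <- read_segment(x, c(52, 58), cache = cache)
  expect_gt(cs$n_reads(), n0)
  expect_length(out, 16)
})
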