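# Shared test helpers: randomized fixture specs, an independent naive
# min-max oracle, and the bundled range-capable HTTP server.

# a randomized but always-valid fixture spec; everything derives from `seed`
random_fixture_spec <- function(seed) {
  withr::with_seed(seed, {
    record_duration <- sample(c(0.5, 1, 2), 1)
    nrec <- sample(4:10, 1)
    nch <- sample(1:4, 1)
    channels <- lapply(seq_len(nch), function(i) {
      spr <- sample(c(2, 5, 16, 50, 100), 1)
      wf <- sample(c("sine", "square", "gaussian-noise", "ramp", "constant"), 1)
      fixture_channel(
        label = sprintf("CH%d SIG", i),
        fs = spr / record_duration,
        waveform = wf,
        # noise is unbounded in the tails: keep sd comfortably inside the
        # +/-200 physical range (deterministic waveforms may swing wider)
        amplitude = if (wf == "gaussian-noise") sample(c(1, 10, 25), 1) else
          sample(c(1, 10, 80), 1),
        physical_min = -200, physical_max = 200,
        digital_min = -2048L, digital_max = 2047L
      )
    })
    fixture_spec(seed = seed, duration_s = nrec * record_duration,
                 record_duration_s = record_duration, channels = channels,
                 patient_id = sprintf("P%06d X X X", sample.int(999999, 1)))
  })
}

# independent oracle: brute-force per-bucket min/max scan
naive_minmax <- function(timestamps_ms, values, f, anchor_ms) {
  rel <- (timestamps_ms - anchor_ms) / 1000
  nb <- floor(max(rel) * f + 1e-6) + 1
  out <- NULL
  for (k in seq_len(nb) - 1) {
    inb <- rel >= k / f - 1e-9 & rel < (k + 1) / f - 1e-9
    if (!any(inb)) next
    out <- rbind(out, c(ts = anchor_ms + k * 1000 / f,
                        min = min(values[inb]), max = max(values[inb])))
  }
  out
}

# start a local range-capable HTTP server for `dir`; stopped automatically
# when the caller's frame exits
local_fixture_server <- function(dir, ranges = TRUE) {
  srv <- start_fixture_server(dir, ranges = ranges)
  withr::defer(srv$stop(), envir = parent.frame())
  # wait until the server actually answers
  for (i in 1:100) {
    ok <- tryCatch({
      curl::curl_fetch_memory(sprintf("http://127.0.0.1:%d/", srv$port))
      TRUE
    }, error = function(e) FALSE)
    if (ok) break
    Sys.sleep(0.05)
  }
  srv
}

# exact physical values the generator implies for a channel
ground_truth_physical <- function(gt, i) {
  digital_to_physical(gt$digital[[i]], gt$sigs[[i]])
}
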