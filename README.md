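# edflazy

Lazy, segment-wise access to EDF/EDF+ biosignal recordings in R — built for
polysomnography-scale files (a whole-night sleep recording is typically
300–500 MB) that you do not want to load whole.

## What it does

EDF stores multichannel time series as a 256-byte static header, 256 bytes of
per-signal dynamic header, and fixed-duration *records* of interleaved 16-bit
samples. Because the layout is chronological, any time range
`[start_s, end_s)` maps to one contiguous, record-aligned byte range:

```
first_record = floor(start_s / record_duration_s)
last_record  = ceil(end_s  / record_duration_s) - 1
offset       = header_bytes + first_record * record_size
```

`edflazy` exploits this to read only what is displayed or analyzed, through
pluggable *loading strategies* (local file seek/read, or single HTTP range
requests against any range-capable server), with a prefetch cache that keeps
±2 viewport widths of signal around the current window.

On top of that core it provides:

* **Min–max decimation** — a signal sampled at `fs` Hz drawn at `f` pixel
  columns per second only needs each column's minimum and maximum:
  the stored fraction is `2f/fs`, eliminating `(1 − 2f/fs)·100` % of samples
  (a 500 Hz EEG channel at 40 columns/s: 84 %) while painting pixel-identical
  extents.
* **Channel-label harmonization** — vendor labels (`"EEGC4-A1"`,
  `"LEGBEINLI"`) are mapped to EDF+ standard texts (`"EEG C4-A1"`,
  `"EMG LAT"`) through a curated CSV table; unknown labels pass through
  flagged, never guessed.
* **Pseudonymization** — the 80-byte patient-identification field (the only
  field intended to carry identity) is replaced by a generated pseudonym;
  the original↔pseudonym mapping lives in a persistent, exportable CSV
  key-value store. Every other byte of the file is copied verbatim.
* **JSON events** — annotations (apnea episodes, artifacts, sleep stages) as
  one JSON object keyed by UNIX millisecond timestamps, with edit operations
  (add/move/resize/remove), external-event ingestion, and a hypnogram
  validator for 30 s epoch scoring (stages W, N1, N2, N3, R).
* **Synthetic fixtures** — a deterministic EDF generator (known waveforms,
  exact digital ground truth, byte-identical per seed), including a 16-channel
  PSG-like spec; all tests run offline against generated data.
* **A CLI** (`inst/cli/edflazy`) with subcommands `info`, `slice`,
  `compress`, `harmonize`, `pseudonymize`, `events`, `render`,
  `generate-fixture`, `serve-fixtures`.

## Worked example

```r
library(edflazy)

# a deterministic 16-channel PSG-like recording
f <- tempfile(fileext = ".edf")
generate_edf(generate_psg_like(seed = 7, duration_s = 20), f)

x <- open_edf(f)        # reads only the headers (two strategy reads)
x
#> EDF recording: 16 signal(s), 20 record(s) x 1 s = 20 s
#>   start: 2019-01-01 00.00.00  patient: "X X 01-JAN-1985 X"
#>   source: local:/tmp/....edf

# one 30 s epoch's worth of pixels: 40 columns per data-second
columns_per_second(1200, 30)          #> 40
samples_per_column(500, 1200, 30)     #> 12
compression_gain(500, 40)             #> 84

# lazy, decimated read of seconds 5-15 at 40 buckets/s
s <- get_data(x, c(5, 15), frequency = 40)
s[[1]]
#> channel 1 [EEG C4-A1]: 400 point(s), min-max @ 40/s

# harmonize the vendor labels
harmonize(c("EEGC4-A1", "LEGBEINLI", "SPO2"))[, c("raw", "standard", "matched")]
#>         raw  standard matched
#> 1  EEGC4-A1 EEG C4-A1    TRUE
#> 2 LEGBEINLI   EMG LAT    TRUE
#> 3      SPO2      SaO2    TRUE

# pseudonymize before the file leaves the machine
store <- pseudonym_store(seed = 1)
pseudonymize_file(f, sub("\\.edf$", "_anon.edf", f), store)
```

The numbers above are what the code prints: 40 pixel columns per second for a
30 s epoch at 1200 px, 12 whole 500 Hz samples overlaying per column, and an
84 % reduction in stored values from min–max decimation at that column rate —
the arithmetic that makes browser-scale rendering of multi-hundred-MB
recordings feasible.

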