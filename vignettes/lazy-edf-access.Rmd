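---
title: "Lazy segment access, min-max decimation and annotation for EDF recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lazy segment access, min-max decimation and annotation for EDF recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edflazy)
```

## The problem

Polysomnography produces whole-night, multi-sensor recordings — EEG, EOG,
EMG, ECG, respiration, oximetry — almost universally exported as EDF/EDF+.
A routine recording has at least 16 signals and runs to hundreds of
megabytes. Visual review works one 30 s epoch at a time, so at any moment
only a sliver of the file is needed; loading the file whole is wasteful
locally and infeasible over a network. `edflazy` implements the data layer
of such a reviewer as a testable, headless R library: time ranges are
translated to byte ranges and fetched on demand, decimated to display
resolution, harmonized, annotated and pseudonymized.

## The byte-range model

EDF's layout makes lazy access exact rather than heuristic. A file is

1. a 256-byte static header (patient, recording, start date/time, record
   count and duration, signal count),
2. 256 bytes per signal of dynamic header (label, calibration ranges,
   samples per record), stored field-by-field across signals,
3. `num_records` *records*, each holding every channel's samples for one
   fixed slice of time, appended channel after channel, as little-endian
   16-bit two's-complement integers.

With `record_size = 2 · Σ samples_per_record`, the half-open time range
`[start_s, end_s)` is covered exactly by records
`floor(start/dur) … ceil(end/dur) − 1`. We *expand outward* to record
boundaries and trim afterwards, never round to the nearest record: nearest
rounding could drop requested samples, outward expansion costs at most one
record of slack on each side. Samples are calibrated to physical units by
the per-signal affine map

$$p = p_{min} + (d - d_{min})\,\frac{p_{max}-p_{min}}{d_{max}-d_{min}},$$

exact at both calibration endpoints.

Reads go through a *loading strategy* — `read(offset, length)` plus
`size()` — with local-file and HTTP implementations. The HTTP strategy
issues one single-range request per read and insists on a 206 response of
the requested length; a server that ignores `Range` and ships the whole
body is reported as a capability error, never silently buffered (silently
accepting the full body would defeat the entire point of lazy access).
The strategy contract is the extension point where a peer-to-peer transport
would plug in; that transport itself is out of scope here.

### Prefetch cache

Scrolling reviewers move mostly in small steps, so the cache keeps a buffer
of two viewport widths on each side of the shown span: after
`ensure_window(cache, t)` the record-aligned, clipped span
`[t.start − 2W, t.end + 2W]` is covered (W = viewport width), using at most
one strategy read per missing side, and bytes outside the span are evicted.
Reads inside the buffered span touch no strategy at all; the tests assert
this with a counting strategy wrapper. Cache granularity — the spec space
left this open — is a single contiguous record-aligned interval, trimmed
exactly to the prefetch span (within the one-record alignment slack), which
matches how a single scrolling viewport actually accesses the file.

## Min-max decimation

A 500 Hz channel drawn into a 30 s window of 1200 px has 40 columns per
data-second: 12 whole samples overlay in each column and paint one vertical
extent. Drawing only each column's minimum and maximum paints the same
extent; at bucket rate `f` the stored fraction is `2f/fs` — for 500 Hz at
40 buckets/s an 84 % reduction.

The frequency parameter `f` counts *buckets* (min-max pairs) per second,
not stored values: stored values per second are `2f`. The alternative
reading (f counts values, so f/2 pairs) would break the pixel-column
arithmetic above, which is the use the parameter exists for; this choice is
deliberate and documented rather than obvious.

Numerical choices:

* bucket `k` spans `[start + k/f, start + (k+1)/f)`, timestamps anchored at
  the bucket start — deterministic and invertible to the bucket index;
* empty buckets are omitted; a partial trailing bucket keeps the min/max of
  its remaining samples (no data loss at window edges);
* channels already at or below `f` pass through untouched;
* the min/max pair is treated as unordered extremes — intra-bucket ordering
  is not preserved (it does not affect the drawn extent);
* re-compressing at the same `f` is a no-op, so pipelines may decimate
  defensively.

**Boundary tolerance.** Timestamps are absolute epoch milliseconds (~10^12),
where a double carries ~2.4·10⁻⁴ ms of quantization; a sample nominally on
a bucket boundary can land infinitesimally below it. Bucket classification
therefore adds 1 µs before flooring — far above the representation error,
far below any genuine sample offset at biosignal rates (≥ 1 ms between
samples up to 1 kHz). Without this, raw and decimated renderings disagree
on boundary samples; with it, the per-pixel-column extents from raw and
decimated input are bit-identical, which the acceptance suite checks.

## Rendering

`render_window()` is a static raster renderer: one stacked panel per
channel, each pixel column drawn as a segment spanning the column's true
extent, events overlaid as translucent spans. Interactive concerns
(panning, cursors, live collaboration) belong to a browser layer and are
out of scope. Vertical scaling defaults to per-channel symmetric limits
around the window mean — nothing in the source format prescribes a scaling,
so the choice optimizes determinism and testability. The renderer reads
only the covering byte range of its window; runtime is bounded by window
size, not file size.

## Harmonization

EDF+ defines standard label texts but compliance is low; the same
derivation appears as `C4-A1`, `EEGC4-A1`, `EEG C4-A1`, or as vendor
inventions like `LEGBEINLI` (left anterior tibialis EMG). Lookup keys are
normalized — uppercase, trimmed, internal whitespace collapsed, one leading
modality token (EEG/EMG/EOG/ECG) with separators stripped unless the label
*is* the token — and matched against a CSV table
(`variant,standard,category,note`). Every standard is its own key, so
harmonization is idempotent and standards are fixed points. Unmatched
labels return unchanged with `matched = FALSE`: in a clinical archive an
unrecognized label is information, and guessing would silently corrupt
montages. The bundled seed table carries the well-known equivalences plus
standard self-entries; site-specific tables (the full curated lists run to
hundreds of variants) load from the same CSV format. The normalization
rules are inferred from the variant patterns, not taken from a published
rule set — they are documented here as this package's own convention.

## Pseudonymization

Only the 80-byte patient field of the static header is intended to carry
identity. Pseudonymization replaces that whole field — name, birth date and
any structured subfields at once, the simplest correctness argument — with
a 12-character string over an unambiguous uppercase+digit alphabet
(no I/L/O/0/1), and by default blanks the free-text recording field.
All other bytes are copied verbatim; the tests verify this by byte diff.
The mapping store is a CSV key-value file (`original, pseudonym,
created_at`), injective in both directions, persistent across restarts,
exportable and re-importable with conflict detection. The store keeps its
own seedable RNG stream and never perturbs the session RNG. Start dates are
quasi-identifying but left unmodified by default — shifting them silently
would break alignment with external event files; deployments can scrub the
recording field and maintain date policy outside the tool. Disabled mode
copies byte-identically, leaving the privacy decision with the sender.
Cryptographic (HMAC) pseudonymization and k-anonymity are non-goals.

## Events

Events are interchanged as a single JSON object keyed by decimal UNIX
millisecond timestamps. The *literal* dialect maps the key to a label
string; the *extended* dialect (this package's documented extension, not a
reconstruction of any particular tool's format) maps it to
`{label, end_ms, channel, source}`. Export emits keys in ascending numeric
order, so output is deterministic; an object cannot hold two events at one
timestamp, so colliding keys are nudged by +1 ms with a warning — explicit
and logged rather than silent. The literal dialect drops range and channel
information; the tests assert exactly that lossiness and nothing more.

Sleep-stage scoring reuses the same event model: stages W/N1/N2/N3/R as 30 s
range events on the epoch grid, with `validate_hypnogram()` checking
alignment, length, overlap and coverage. One event model serving both
scoring and marking keeps merge/dedup semantics uniform; externally
produced events (artifact or apnea detectors) merge with deduplication on
`(start, end, label, channel)` while retaining their source tag.

## Synthetic data: what it emulates, what it does not

The fixture generator emits structurally exact EDF: correct field widths
and offsets, record interleaving, mixed sampling rates, 16-bit calibration,
and exact per-channel digital ground truth; the same seed yields a
byte-identical file. The PSG-like spec mirrors the *shape* of a routine
recording — 16 channels, high-rate EEG/EOG/EMG/ECG next to low-rate
airflow/effort/oximetry, vendor-variant labels — at 30 s instead of 8 h so
the suite runs at desk scale (a scale flag is deliberately absent; the
format cost model is linear in records, so nothing new is exercised by
size alone).

The waveforms (sine, square, Gaussian noise, per-record ramp, constant) are
*not* physiological. A green suite therefore establishes byte-level and
arithmetic correctness — parsing, slicing, calibration, decimation,
harmonization, privacy — on valid EDF of realistic structure; it says
nothing about robustness to the malformed headers real devices sometimes
emit (those are rejected with named errors, not repaired), and nothing
about clinical interpretability of rendered signals.

## Degenerate inputs and deliberate rejections

* `num_records == −1` (the "still recording" streaming sentinel) is
  rejected with a distinct error: this is a post-hoc review tool, and
  guessing the record count from file size would make behavior depend on
  transport state.
* EDF-D (discontinuous) files and BDF (24-bit) are out of scope;
  `EDF Annotations` channels are detected by label and excluded from signal
  operations, but their TAL byte stream is not parsed — JSON is the event
  format here precisely because the embedded channels are cumbersome.
* Header text fields are trimmed of trailing spaces on decode, but the
  original padded bytes are retained, so re-encoding an unmodified header
  is byte-identical even for files with unusual numeric padding — the
  property that lets the pseudonymizer guarantee "only the identity fields
  changed" by byte diff.
* Two-digit years follow the EDF+ clipping convention: `yy ≥ 85 → 19yy`,
  else `20yy`.
* Dates/times are interpreted as UTC; EDF carries no timezone, and any
  fixed convention beats a machine-local one.

## Acceptance surface

`scripts/acceptance.R` recomputes, from the running package, the
display-arithmetic quantities: 40 columns per second (1200 px / 30 s),
12 whole 500 Hz samples per column, the 84 % stored-value reduction at that
column rate (measured live on a generated 500 Hz recording and
cross-checked against the closed form), and the 16 ms frame-period floor of
a 60 Hz display. The property-based criteria — generate/parse round trips,
lazy-read equality with whole-file parses, local/HTTP strategy equivalence
against the bundled range-capable test server, decimation against a naive
per-bucket scan, raw/decimated rendering equivalence, the ±2W cache
contract, pseudonymization byte diffs, and the printed harmonization
equivalences — run in `tests/testthat/test-acceptance.R`, one test per
criterion.
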