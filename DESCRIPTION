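Package: edflazy
Title: Lazy Segment-Wise Access, Decimation and Annotation Tools for
    EDF/EDF+ Biosignal Recordings
Version: 0.1.0
Authors@R: person("somnonetz", "maintainers", email = "edflazy@example.org",
    role = c("aut", "cre"))
Description: Read, slice and render polysomnography-scale EDF and EDF+
    recordings without loading whole files: time ranges are translated to
    record-aligned byte ranges and fetched through pluggable loading
    strategies (local file, HTTP range requests), with a viewport prefetch
    cache.  Includes min-max decimation to display resolution, channel-label
    harmonization against the EDF+ standard texts, header pseudonymization
    with a persistent exportable mapping, a timestamp-keyed JSON event
    format for sleep scoring and event marking, a deterministic synthetic
    EDF generator, and a command-line interface with static window
    rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    curl,
    jsonlite,
    withr,
    tools,
    utils,
    stats,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
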