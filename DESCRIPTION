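Package: chunkdejitter
Title: Timestamp Dejittering and Timing-Precision Evaluation for
    Chunked Wireless EEG Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for correcting per-sample timestamps of wireless EEG
    recordings delivered in buffered transport chunks, as produced by
    Bluetooth dongles with long serial buffer intervals. Implements a
    chunk-wise dejittering algorithm (chunk-boundary detection,
    within-chunk extrapolation from the chunk reception timestamp at the
    nominal sampling rate, and in-place shifting of short chunks that
    overlap their predecessor), the conventional segment-wise linear
    dejitter used by XDF importers, and a square-wave timing-oracle
    analysis (epoch extraction around stimulus markers, half-maximum
    onset detection, per-trial latency, lag and jitter). A seedable
    simulator of the buffered acquisition chain provides ground truth
    for end-to-end validation, and a minimal XDF reader/writer plus a
    command-line interface round out the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tibble,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
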