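# chunkdejitter

Timestamp correction and timing-precision evaluation for chunked wireless
EEG streams.

Low-cost wireless EEG amplifiers often deliver their samples through a
buffered serial transport: instead of arriving one by one, samples arrive
in *chunks* of roughly half a second, and the acquisition software stamps
every sample in a chunk with the chunk's reception time. The conventional
timestamp correction applied by XDF importers — a linear fit of timestamp
against sample index per gap-free segment — assumes small symmetric
stamping noise and goes badly wrong on this structure: single-trial event
latencies become erratic and vary from run to run.

This package implements:

* **`chunk_dejitter()`** — chunk-wise timestamp correction: chunk
  boundaries are detected from large sample-to-sample raw timestamp
  differences, each chunk's timestamps are extrapolated from its reception
  timestamp at the nominal sampling rate
  (`corrected[s+k] = T_c + k / rate`), and undersized ("short") chunks
  whose extrapolation overlaps the previous chunk are shifted right in
  place, in temporal order, to sit one nominal interval after it.
* **`regular_dejitter()`** — the segment-wise linear baseline, for
  single-packet transports and for comparison.
* **Timing-oracle metrics** — `extract_epochs()` (−200…+800 ms windows
  around stimulus markers), `detect_latencies()` (per-trial latency = time
  from marker to the amplitude exceeding half the maximum of the
  trial-averaged response; **lag** = mean latency, **jitter** = sample SD),
  `correct_lag()` and `summarize_runs()`.
* **A seedable simulator** of the whole loopback rig —
  `simulate_recording()` / `simulate_clean_recording()`: 10 Hz square wave
  of 5 ms pulses on one channel, marker stream at intended playback times,
  and chunked Bluetooth-style transport with configurable chunk sizes
  (59–61 samples at 125 Hz, 119–121 at 250 Hz), short-chunk rate, constant
  transport delay and onset jitter — with full ground truth for
  validation.
* **XDF I/O and a CLI** — `read_xdf()` / `write_xdf()` /
  `load_recording()` / `run_timing_report()`, plus a command-line tool
  (`inst/cli/chunkdejitter`) with `simulate`, `dejitter` and
  `timing-report` subcommands.

## Worked example

Simulate eight timing-test runs at 250 Hz with a 48 ms transport buffer
(12-sample chunks), a 20 ms transport delay, a 10 ms hardware lag and 1 ms
onset jitter; correct the timestamps chunk-wise and measure latency, lag
and jitter:

```r
library(chunkdejitter)

mk <- function(s) simulate_recording(sim_config(
  rate = 250, duration = 43, n_trials = 400, marker_start = 1.5,
  chunk_size_choices = 12, transport_delay = 0.02, hardware_lag = 0.01,
  onset_jitter_sd = 0.001, seed = s))

rec <- mk(1)
fixed <- chunk_dejitter(rec$stream)
sum(fixed$chunks$shifted)               # 24 short chunks shifted in place

epochs <- extract_epochs(fixed$stream, rec$markers)
detect_latencies(epochs)
#> <timing_result: lag 75.99 ms, jitter 0.83 ms, 400/400 trials used>

run_timing_report(lapply(1:8, mk), method = "chunk",
                  label = "sim 250 Hz, 48 ms buffer")$summary
#> # A tibble: 1 x 7
#>   configuration  method n_runs mean_lag_ms mean_jitter_ms lag_sd_ms jitter_sd_ms
#> 1 sim 250 Hz, 4… chunk       8        76.0          0.864    0.0406       0.0658
```

The measured lag (~76 ms) decomposes exactly as transport delay (20 ms) +
chunk buffering ((12 − 1)/250 = 44 ms) + hardware lag (10 ms) + ~2 ms mean
sample quantization; it is constant across runs (SD 0.04 ms), so a single
`correct_lag()` per run aligns the signal with the marker clock. The
jitter (~0.86 ms) is the injected 1 ms onset jitter combined with the
4 ms/√12 quantization floor over the finite trial sample.

The same comparison at 125 Hz with full-size (~480 ms) chunks is where the
methods separate: across 8 constant-delay runs the across-run lag SD is
0 ms under chunk dejittering while the segment-wise linear correction on
the same streams varies by ~1.5 ms run to run (and by far more once chunk
sizes vary) — see the acceptance script below.

From the shell:

```sh
Rscript inst/cli/chunkdejitter simulate --config config.yaml \
    --out run1.xdf --seed 1
Rscript inst/cli/chunkdejitter dejitter --in run1.xdf --method chunk \
    --out run1-fixed.xdf
Rscript inst/cli/chunkdejitter timing-report --in 'run*.xdf' \
    --method chunk --out report/ --plot
```

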