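---
title: "Dejittering chunked EEG streams and measuring timing precision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dejittering chunked EEG streams and measuring timing precision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chunkdejitter)
```

## The problem

Wireless EEG amplifiers stream samples to a recording computer over
Bluetooth. When the receiving driver buffers the serial stream (for
example, an FTDI USB-serial buffer latency timer set to a long interval),
samples arrive in bursts: a *chunk* of roughly half a second of data is
delivered at once, and the acquisition software stamps every sample in the
burst with (nearly) the reception time. The raw per-sample timestamps then
show a characteristic staircase: near-zero sample-to-sample differences
inside a chunk and a jump of about one chunk duration between chunks. At
125 Hz the observed chunk sizes are 59–61 samples, at 250 Hz 119–121.

Event-related potential (ERP) analyses need per-sample timestamps accurate
to a few milliseconds, so these raw stamps must be replaced by a
regularized time base. Two corrections are implemented:

* **Regular (segment-wise linear) dejitter** — `regular_dejitter()`. The
  recording is split at raw gaps larger than `gap_threshold` (default 1 s)
  and each segment's timestamps are replaced by an ordinary-least-squares
  fit of timestamp against sample index. This is the correction XDF
  importers apply on load. It assumes small, symmetric stamping noise; on
  chunked streams the fitted line runs through the middle of each stamp
  cluster and individual samples end up wrong by up to half a chunk
  (~±240 ms at 125 Hz), differently from run to run.
* **Chunk dejitter** — `chunk_dejitter()`. Chunk boundaries are detected
  where the raw sample-to-sample difference exceeds
  `boundary_factor / nominal_rate`; within each chunk, timestamps are
  extrapolated forward from the chunk's first raw stamp (the reception
  time) at the nominal rate, `corrected[s + k] = T_c + k / rate`. A second
  pass repairs *short chunks*: an undersized burst whose extrapolated
  span overlaps its predecessor (and leaves a gap to its successor) is
  shifted right, in temporal order so consecutive short chunks cascade,
  to start one nominal interval after the previous chunk's corrected end.

The nominal rate always comes from the stream metadata and is never
re-estimated from the data: the amplifier's sampling clock is the one
trustworthy clock in the chain.

## The timing oracle

Timing precision is measured with a loopback design: the stimulus PC plays
a periodic square wave (10 Hz, 5 ms pulses) whose voltage is fed from the
audio jack straight into one amplifier channel, while the stimulus
software emits a marker at each intended playback time. Because the signal
is physical, the delay between marker and recorded voltage rise is pure
acquisition-chain latency.

`extract_epochs()` cuts one window per marker from the corrected
recording, `[-200, +800)` ms relative to the marker, aligned on sample
indices so every trial has the same length. `detect_latencies()`
baseline-corrects each trial by its pre-stimulus mean, averages the trials,
takes half the post-stimulus maximum of the average as threshold, and
reports per-trial latency as the relative time of the first post-stimulus
sample above threshold — at sample resolution, with no sub-sample
interpolation, so the quantization step is `1/rate` (8 ms at 125 Hz, 2 ms
at 500 Hz). Then

* **lag** = mean of the single-trial latencies (a constant offset,
  removable by `correct_lag()`, which subtracts it from the corrected
  timestamps), and
* **jitter** = sample standard deviation (n − 1) of the latencies (the
  irreducible timing noise that smears ERP averages).

Trials with no threshold crossing are reported missing and excluded from
both summaries. `summarize_runs()` averages lag and jitter across the runs
of a configuration without weighting by trial count, and reports their
across-run SDs (0 for a single run).

Two conventions were genuinely open and are fixed as follows: jitter uses
the sample (n − 1) SD, and the half-maximum is taken on baseline-corrected
amplitude. Per-configuration summaries are means across runs, not pooled
trials; pooling can be emulated by concatenating latency tables from the
`timing_report` object.

## What the simulator emulates

`simulate_recording()` generates the whole chain with known ground truth:

* markers every `1/pulse_rate` s starting at `marker_start` (default
  0.5 s);
* physical pulse onsets at marker + delay, where the delay is Gaussian
  with mean `hardware_lag` (default 30 ms) and SD `onset_jitter_sd`
  (default 1 ms), truncated at 0 because a physical delay cannot be
  negative — with the defaults the truncation is never active;
* the square wave sampled on the exact `k/rate` grid plus Gaussian sensor
  noise (`noise_sd`, default 1 µV against a 100 µV pulse);
* chunk sizes drawn from `chunk_size_choices` (defaults follow the
  observed ranges: {59, 60, 61} at 125 Hz, {119, 120, 121} at 250 Hz,
  otherwise ~0.48 s of samples); with probability `short_chunk_prob`
  (default 0.02 — short chunks are a documented occurrence whose rate is
  not, so a rate of one every few minutes was chosen) a chunk is truncated
  to `short_chunk_fraction` of its drawn size, the remaining samples
  starting the next chunk (truncation only; no sample loss);
* each chunk delivered at the generation time of its last sample plus a
  constant `transport_delay` (default 50 ms), its samples' raw stamps
  spaced by `intra_chunk_stamp_spacing` (default 0.2 ms, small against
  the boundary threshold). A recording that stops mid-buffer has its
  partial final chunk delivered when the buffer period elapses (the
  flush-timer behaviour of a buffered driver); delivering it at its last
  sample's generation time would place it inside the previous chunk's
  stamp cluster, where no detector could see it.

`simulate_clean_recording()` is the single-packet reference transport:
every sample is delivered individually with the constant delay, plus
optional zero-mean stamping noise (`stamp_noise_sd`) — the regime in which
the segment-wise linear dejitter is the right model.

All randomness flows from `seed`; identical seeds give bit-identical
recordings.

An important structural consequence of the reception-anchored model: a
chunk's first sample is stamped when its *last* sample has been generated,
so after chunk dejittering every sample carries a constant offset of
`transport_delay + (n_chunk − 1)/rate` — about half a second at 125 Hz
with 60-sample chunks. The large lag of a buffered transport is thus
reproduced, and it exceeds the 100 ms stimulus period, so first-crossing
latencies are aliased modulo the period. This mirrors the physical rig;
lag *constancy* (the property that matters, since a constant is removable)
is unaffected.

What the simulator does **not** emulate: amplifier analog front-ends and
input-referred noise spectra, sampling-clock drift relative to the
recorder clock, clock resets, marker-stream clock offsets (alignment is
assumed done by the acquisition layer), packet loss, and the physical
cause of short chunks (only truncation is modelled). Passing tests
therefore validate the correction algorithms and metrics under an
idealized, deterministic transport, not amplifier hardware.

## Numerical and design choices

* `boundary_factor = 2`: within-chunk stamp spacing is ~0.2 ms and
  inter-chunk gaps are ~0.5 s, so any multiplier in a wide band works;
  twice the nominal interval is the conservative midpoint. Raw gaps more
  negative than the threshold (recorder clock resets) also open a new
  chunk/segment, and no re-alignment is attempted across them.
* `overlap_tolerance = 0`: any chunk whose extrapolated start does not
  strictly exceed the previous corrected end is shifted. Overlaps manifest
  as strictly negative corrected differences, so a zero tolerance is the
  natural boundary.
* The shift delta places a short chunk immediately after its predecessor
  (one nominal interval after the corrected end), trusting earlier
  reception stamps over later ones; the delta applied to each chunk is
  recorded in the chunk map (`shift_s`) for audit. Closing the gap to the
  *following* chunk instead would be consistent with the same observed
  difference pattern; with the reception-anchored transport above, both
  rules land the short chunk's samples on the same uniform grid.
* The "robust linear interpolation" of XDF importers is implemented as
  plain OLS per segment; the robustness scheme of any particular importer
  is not specified, and on segment sizes of minutes with millisecond
  noise the difference is negligible.
* Epoch windows are half-open `[start, end)` and trial lengths are fixed
  in samples, so epoch matrices are deterministic.
* Degenerate inputs: single-sample segments pass their timestamp through;
  streams with fewer than 2 samples, nonpositive rates, empty marker sets
  and flat (no-response) averages raise errors rather than returning
  nonsense.

## Validation experiments and their problem sizes

The test suite validates the toolkit end to end against simulator ground
truth; sizes follow the timing-test design of ~400 stimuli per run:

* *Chunk recovery*: 20 seeded runs (125 and 250 Hz, 40 s); the detected
  partition must equal the emitted one exactly.
* *Extrapolation identity*: corrected within-chunk spacing equals the
  nominal interval to ~1e-12 s (floating-point round-off on absolute
  times of tens of seconds) and corrected stamps strictly increase with
  short chunks injected.
* *Lag-variance elimination*: 8 runs per rate, constant transport delay
  and hardware lag, zero onset jitter, fixed nominal chunk size with 2%
  short chunks. Across-run lag SD under chunk dejitter must be < 0.1 ms
  while the regular dejitter on the same streams is strictly larger.
  Stimulation starts at 1.5 s, after the first transport chunk, so all
  epochs lie in the steady-state region: the first chunk of a recording
  has no predecessor to anchor a shift, so recording-onset trials would
  mix correction regimes — the loopback analogue of discarding the first
  seconds of a recording. A fixed nominal size is used because random
  size variation adds ±1–2 samples of reception-anchor quantization per
  chunk, which is real but unrelated to the transport-delay variance this
  experiment isolates.
* *Jitter recovery*: injected onset jitter σ ∈ {1, 2, 5} ms at 500 Hz,
  400 trials, 20 repetitions; measured jitter must match
  √(σ² + q²), q = (1000/rate)/√12 ms (the uniform quantization SD),
  within 3 Monte-Carlo SEs, and be monotone in σ. The transport delay is
  20 ms here so that total delay plus the 3.5σ jitter tail stays clear of
  the 100 ms stimulus period — a validity condition of the closed form,
  which assumes consecutive trials do not overlap.
* *Oracle equivalence*: `regular_dejitter()` agrees with an independent
  closed-form per-segment OLS on 100 random instances to ≤ 1e-9 s.

`scripts/acceptance.R` re-runs these experiments from scratch against the
installed package and writes the measured quantities as JSON.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(rate = 125, duration = 43, n_trials = 400,
                  marker_start = 1.5, chunk_size_choices = 60,
                  onset_jitter_sd = 0, seed = 1)
rec <- simulate_recording(cfg)

fixed <- chunk_dejitter(rec$stream)
summary(fixed$chunks$n_samples)

epochs <- extract_epochs(fixed$stream, rec$markers)
detect_latencies(epochs)
```

## Known limitations

* Latencies are quantized to the sample interval; at 125 Hz this floor
  (8/√12 ≈ 2.3 ms SD) dominates measured jitter.
* When total acquisition lag exceeds the stimulus period, single-trial
  latencies alias modulo the period; lag estimates are then offsets into
  the pulse train rather than absolute delays. Use a slower pulse rate or
  correct a known lag first if absolute values are needed.
* The XDF reader supports the numeric/string subset of the format written
  by this package and by common LSL recorders; clock-offset chunks are
  ignored rather than applied.
* The chunk detector assumes within-chunk stamp spacing well below the
  nominal interval; transports that smear stamps across most of the
  interval need a larger `boundary_factor` margin analysis.
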