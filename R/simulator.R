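#' Simulator configuration for the timing-test acquisition chain
#'
#' Describes one timing-test recording: a periodic square-wave stimulus
#' (default 10 Hz, 5 ms pulses) recorded on one channel, a marker stream at
#' the intended playback times, and a buffered transport that delivers
#' samples in chunks whose raw timestamps cluster at chunk reception.
#'
#' The physical stimulus onset of trial k is
#' `marker_k + hardware_lag + jitter_k`, where the total delay
#' `hardware_lag + jitter_k` is drawn from a Gaussian with mean
#' `hardware_lag` and SD `onset_jitter_sd`, truncated at 0 (a physical
#' delay cannot be negative; with the defaults the truncation is inactive).
#'
#' Transport: samples are grouped into chunks whose sizes are drawn from
#' `chunk_size_choices` (with `chunk_size_probs`); with probability
#' `short_chunk_prob` a chunk is truncated to `short_chunk_fraction` of its
#' drawn size (the remaining samples start the next chunk, so no samples
#' are lost). Each chunk is delivered at the generation time of its last
#' sample plus `transport_delay`; the raw timestamps of its samples are the
#' delivery time plus `0:(n-1) * intra_chunk_stamp_spacing`.
#'
#' @param rate sampling rate in Hz (125/250/500 typical).
#' @param duration recorded duration in seconds; samples lie on the exact
#'   grid `k/rate`, `k = 0 .. rate*duration - 1`.
#' @param pulse_rate square-wave frequency in Hz (default 10).
#' @param pulse_width pulse duration in seconds (default 0.005); must be
#'   shorter than `1/pulse_rate`.
#' @param pulse_amplitude pulse height in microvolts.
#' @param noise_sd additive Gaussian sensor noise SD in microvolts.
#' @param hardware_lag mean stimulus-to-signal delay in seconds.
#' @param onset_jitter_sd SD of the trial-to-trial onset jitter in seconds.
#' @param n_trials number of markers; default `floor(duration*pulse_rate)`.
#' @param marker_start time of the first marker in seconds (default 0.5).
#' @param chunk_size_choices integer vector of nominal chunk sizes; default
#'   `59:61` at 125 Hz, `119:121` at 250 Hz, otherwise sizes within one
#'   sample of `round(0.48 * rate)`.
#' @param chunk_size_probs sampling probabilities (default uniform).
#' @param short_chunk_prob probability a chunk is truncated (default 0.02).
#' @param short_chunk_fraction fraction of the drawn size kept (default 0.5).
#' @param transport_delay constant transport delay in seconds.
#' @param intra_chunk_stamp_spacing within-chunk raw stamp spacing in
#'   seconds (default 0.2 ms, small against the chunk-boundary threshold).
#' @param stamp_noise_sd SD in seconds of the zero-mean stamping noise used
#'   by [simulate_clean_recording()] (ignored by the chunked transport).
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rate = 125, duration = 40, pulse_rate = 10,
                       pulse_width = 0.005, pulse_amplitude = 100,
                       noise_sd = 1, hardware_lag = 0.03,
                       onset_jitter_sd = 0.001, n_trials = NULL,
                       marker_start = 0.5, chunk_size_choices = NULL,
                       chunk_size_probs = NULL, short_chunk_prob = 0.02,
                       short_chunk_fraction = 0.5, transport_delay = 0.05,
                       intra_chunk_stamp_spacing = 2e-4,
                       stamp_noise_sd = 0, seed = 1L) {
  stopifnot(rate > 0, duration > 0, pulse_rate > 0, pulse_width > 0,
            short_chunk_prob >= 0, short_chunk_prob <= 1,
            short_chunk_fraction > 0, short_chunk_fraction <= 1,
            onset_jitter_sd >= 0, noise_sd >= 0, stamp_noise_sd >= 0)
  if (pulse_width >= 1 / pulse_rate) stop("overlapping pulses")
  if (is.null(chunk_size_choices)) {
    chunk_size_choices <- if (rate == 125) 59:61 else if (rate == 250) {
      119:121
    } else round(0.48 * rate) + (-1:1)
  }
  chunk_size_choices <- as.integer(chunk_size_choices)
  stopifnot(all(chunk_size_choices >= 1))
  if (is.null(chunk_size_probs)) {
    chunk_size_probs <- rep(1 / length(chunk_size_choices),
                            length(chunk_size_choices))
  }
  stopifnot(length(chunk_size_probs) == length(chunk_size_choices),
            all(chunk_size_probs >= 0))
  if (is.null(n_trials)) n_trials <- floor(duration * pulse_rate)
  structure(
    list(rate = rate, duration = duration, pulse_rate = pulse_rate,
         pulse_width = pulse_width, pulse_amplitude = pulse_amplitude,
         noise_sd = noise_sd, hardware_lag = hardware_lag,
         onset_jitter_sd = onset_jitter_sd, n_trials = as.integer(n_trials),
         marker_start = marker_start,
         chunk_size_choices = chunk_size_choices,
         chunk_size_probs = chunk_size_probs,
         short_chunk_prob = short_chunk_prob,
         short_chunk_fraction = short_chunk_fraction,
         transport_delay = transport_delay,
         intra_chunk_stamp_spacing = intra_chunk_stamp_spacing,
         stamp_noise_sd = stamp_noise_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Square wave sampled on the exact k/rate grid, plus sensor noise.
# Returns list(values, true_times, onsets).
sim_signal <- function(config) {
  n <- round(config$rate * config$duration)
  true_times <- (seq_len(n) - 1) / config$rate
  markers <- config$marker_start +
    (seq_len(config$n_trials) - 1) / config$pulse_rate
  # total hardware delay, Gaussian truncated at 0
  delay <- stats::rnorm(config$n_trials, config$hardware_lag,
                        config$onset_jitter_sd)
  while (any(delay < 0)) {
    bad <- delay < 0
    delay[bad] <- stats::rnorm(sum(bad), config$hardware_lag,
                               config$onset_jitter_sd)
  }
  onsets <- markers + delay
  values <- numeric(n)
  for (o in onsets) {
    hi <- true_times >= o & true_times < o + config$pulse_width
    values[hi] <- config$pulse_amplitude
  }
  if (config$noise_sd > 0) {
    values <- values + stats::rnorm(n, 0, config$noise_sd)
  }
  list(values = values, true_times = true_times, markers = markers,
       onsets = onsets)
}

#' Simulate a chunked timing-test recording
#'
#' Generates one full timing-test run: the marker stream at intended
#' playback times, the square-wave signal sampled on the exact `k/rate`
#' grid, and raw timestamps as produced by the buffered transport (see
#' [sim_config()] for the transport model). The returned ground truth
#' carries the true per-sample generation times, true per-trial onsets and
#' the emitted chunk partition, so recovery can be verified exactly.
#'
#' @param config a [sim_config()].
#' @return A list with elements `stream` ([sampled_stream()] with raw
#'   timestamps only), `markers` ([marker_stream()]) and `truth` (list with
#'   `true_sample_times`, `true_onset_times`, `marker_times`,
#'   `emitted_chunk_sizes`, `chunk_start_index`, `injected_lag`,
#'   `injected_jitter_sd`).
#' @export
simulate_recording <- function(config) {
  withr::with_seed(config$seed, {
    sig <- sim_signal(config)
    n <- length(sig$values)
    # draw the chunk partition
    sizes <- drawn <- integer(0)
    total <- 0L
    while (total < n) {
      size <- config$chunk_size_choices[
        sample.int(length(config$chunk_size_choices), 1L,
                   prob = config$chunk_size_probs)]
      if (config$short_chunk_prob > 0 &&
          stats::runif(1) < config$short_chunk_prob) {
        size <- max(1L, as.integer(round(size * config$short_chunk_fraction)))
      }
      drawn <- c(drawn, size)
      size <- min(size, n - total)
      sizes <- c(sizes, size)
      total <- total + size
    }
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    delivery <- sig$true_times[ends] + config$transport_delay
    # a recording that stops mid-buffer still waits out the buffer period:
    # the flush timer delivers the partial final chunk when the buffer
    # would have been full, not when its last sample was generated
    last <- length(sizes)
    delivery[last] <- delivery[last] +
      (drawn[last] - sizes[last]) / config$rate
    raw <- numeric(n)
    for (c in seq_along(sizes)) {
      raw[starts[c]:ends[c]] <- delivery[c] +
        (seq_len(sizes[c]) - 1) * config$intra_chunk_stamp_spacing
    }
    list(
      stream = sampled_stream(sig$values, raw, config$rate,
                              channel_labels = "SquareWave"),
      markers = marker_stream(sig$markers),
      truth = list(
        true_sample_times = sig$true_times,
        true_onset_times = sig$onsets,
        marker_times = sig$markers,
        emitted_chunk_sizes = sizes,
        chunk_start_index = starts,
        injected_lag = config$hardware_lag,
        injected_jitter_sd = config$onset_jitter_sd
      )
    )
  })
}

#' Simulate a per-sample ("clean") transport recording
#'
#' Reference behaviour of a single-packet transport: every sample is its
#' own chunk, delivered at its generation time plus the constant
#' `transport_delay`, with optional zero-mean Gaussian stamping noise of
#' SD `stamp_noise_sd` on the raw timestamps. The stimulus, marker and
#' ground-truth structure is identical to [simulate_recording()].
#'
#' @param config a [sim_config()]; `stamp_noise_sd` sets the stamping
#'   noise.
#' @return same structure as [simulate_recording()]; every emitted chunk
#'   has size 1.
#' @export
simulate_clean_recording <- function(config) {
  withr::with_seed(config$seed, {
    sig <- sim_signal(config)
    n <- length(sig$values)
    raw <- sig$true_times + config$transport_delay
    if (config$stamp_noise_sd > 0) {
      raw <- raw + stats::rnorm(n, 0, config$stamp_noise_sd)
    }
    list(
      stream = sampled_stream(sig$values, raw, config$rate,
                              channel_labels = "SquareWave"),
      markers = marker_stream(sig$markers),
      truth = list(
        true_sample_times = sig$true_times,
        true_onset_times = sig$onsets,
        marker_times = sig$markers,
        emitted_chunk_sizes = rep(1L, n),
        chunk_start_index = seq_len(n),
        injected_lag = config$hardware_lag,
        injected_jitter_sd = config$onset_jitter_sd
      )
    )
  })
}
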